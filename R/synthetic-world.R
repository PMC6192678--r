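# Truth-known synthetic world generator. Emulates the statistical structure
# of a large multi-study amplicon survey: an EMPO-like environment
# hierarchy, nested presence structure across richness-ordered samples,
# tip-level environment specificity under cosmopolitan genera,
# Laplace-bounded richness against pH and temperature, bimodal 16S
# copy-number regimes, and heterogeneous sequencing depth. Every generated
# count traces back to a recorded truth, so downstream statistics can be
# validated against planted parameters.

empoBranches <- c("Non-saline", "Saline", "Animal", "Plant")

#' Configuration of a synthetic world
#'
#' @param nSamples number of samples.
#' @param nTags number of tag sequences (tree tips).
#' @param nEnvironmentsL3 number of level-3 environments, assigned
#'   round-robin to the four level-2 branches (Non-saline, Saline, Animal,
#'   Plant); at least 2.
#' @param nStudiesPerEnv studies per environment.
#' @param nu nestedness strength in [0, 1]: fraction of each sample's
#'   richness filled from the top of the global prevalence ranking
#'   (1 = perfectly nested).
#' @param kappa specificity concentration >= 0: a tag's odds of filling a
#'   non-nested slot (and its abundance weight) are multiplied by
#'   \code{exp(kappa)} in its home environment (0 = no specificity).
#' @param genusPoolFraction fraction of the level-3 environments available
#'   to each genus (at least 2 environments); member tags draw their home
#'   uniformly within the genus pool, so a genus is spread over several
#'   environments while each tip concentrates in one.
#' @param richnessEnvelope named list of per-covariate Laplace envelopes
#'   \code{c(mode, scale, amplitude)}; defaults pH (mode 7) and temperature
#'   (mode 10 degrees C). Free-living non-saline samples carry pH,
#'   free-living saline samples carry temperature (mirroring real surveys,
#'   where the two covariates are measured on largely disjoint sample
#'   sets); the sample's richness bound is the envelope at its covariate.
#' @param hostRichnessCap flat richness bound for host-associated samples.
#' @param copyNumberRegimes named per-branch target mean 16S copy number
#'   (defaults: Animal 3.4, others 2.2).
#' @param depthDistribution \code{c(meanlog, sdlog, min)} of the lognormal
#'   sequencing depth, floored at \code{min}.
#' @param noise if \code{FALSE}, skip the multinomial read draw: every
#'   planted presence gets count 1, so the presence matrix equals the
#'   planted one exactly.
#' @param seed integer seed; the whole world is a deterministic function of
#'   the config.
#' @return a \code{WorldConfig} list.
#' @export
worldConfig <- function(nSamples = 500, nTags = 400, nEnvironmentsL3 = 8,
                        nStudiesPerEnv = 2, nu = 0.6, kappa = 3,
                        genusPoolFraction = 0.5,
                        richnessEnvelope = list(
                          ph = c(mode = 7, scale = 2, amplitude = 150),
                          temperature_deg_c = c(mode = 10, scale = 8,
                                                amplitude = 150)),
                        hostRichnessCap = 80,
                        copyNumberRegimes = c(`Non-saline` = 2.2,
                                              Saline = 2.2, Plant = 2.2,
                                              Animal = 3.4),
                        depthDistribution = c(meanlog = log(30000),
                                              sdlog = 0.5, min = 2000),
                        noise = TRUE, seed = 1) {
  cfg <- list(nSamples = nSamples, nTags = nTags,
              nEnvironmentsL3 = nEnvironmentsL3,
              nStudiesPerEnv = nStudiesPerEnv, nu = nu, kappa = kappa,
              genusPoolFraction = genusPoolFraction,
              richnessEnvelope = richnessEnvelope,
              hostRichnessCap = hostRichnessCap,
              copyNumberRegimes = copyNumberRegimes,
              depthDistribution = depthDistribution, noise = noise,
              seed = seed)
  class(cfg) <- "WorldConfig"
  validateWorldConfig(cfg)
  cfg
}

validateWorldConfig <- function(cfg) {
  if (!is.finite(cfg$nu) || cfg$nu < 0 || cfg$nu > 1)
    .stopf("nu must be in [0, 1]")
  if (!is.finite(cfg$kappa) || cfg$kappa < 0)
    .stopf("kappa must be finite and >= 0")
  if (cfg$nEnvironmentsL3 < 2) .stopf("need at least 2 environments")
  amp <- vapply(cfg$richnessEnvelope, function(e) e[["amplitude"]], 0)
  if (any(amp < 1)) .stopf("envelope amplitudes must be >= 1")
  if (cfg$hostRichnessCap < 1) .stopf("hostRichnessCap must be >= 1")
  invisible(TRUE)
}

#' Simulate a random rooted tree
#'
#' Yule-type random bifurcating topology (via \code{\link[ape]{rtree}})
#' with independent exponential branch lengths; deterministic under
#' \code{seed}.
#'
#' @param nTips number of tips (>= 2); labels \code{tag00001}, ...
#' @param seed integer seed.
#' @return a rooted \code{phylo}.
#' @export
generateTree <- function(nTips, seed = NULL) {
  if (nTips < 2) .stopf("nTips must be >= 2")
  withSeed(seed, {
    tr <- ape::rtree(nTips)
    tr$edge.length <- rexp(nrow(tr$edge), rate = 10)
    tr$tip.label <- sprintf("tag%05d", seq_len(nTips))
    tr
  })
}

#' Derive a taxonomy by cutting a tree at decreasing depths
#'
#' Ranks phylum ... genus are defined by clades whose maximum tip-to-tip
#' path length does not exceed the rank's threshold: for each threshold the
#' maximal such clades partition the tips into groups. Because the
#' thresholds decrease, groups nest, so lineages are prefix-consistent by
#' construction. The kingdom rank is a single group.
#'
#' @param tree a rooted \code{phylo}.
#' @param rankDepths five strictly decreasing distance thresholds (phylum,
#'   class, order, family, genus); default fractions of the tree diameter.
#' @return taxonomy data.frame (rows = tip labels, columns = ranks).
#' @export
taxonomyFromTree <- function(tree, rankDepths = NULL) {
  st <- nodeDepthStats(tree)
  diam <- st$maxPath[ape::Ntip(tree) + 1L]
  if (is.null(rankDepths))
    rankDepths <- diam * c(0.55, 0.40, 0.28, 0.16, 0.08)
  if (length(rankDepths) != 5 || any(diff(rankDepths) >= 0))
    .stopf("rankDepths must be 5 strictly decreasing thresholds")
  n_tip <- ape::Ntip(tree)
  kids <- .childrenList(tree)
  tax <- data.frame(kingdom = rep("k__1", n_tip),
                    row.names = tree$tip.label)
  for (r in seq_along(rankDepths)) {
    thr <- rankDepths[r]
    group <- integer(n_tip)
    g <- 0L
    # maximal clades (closest to the root) with max tip-to-tip <= thr
    stack <- n_tip + 1L
    while (length(stack)) {
      node <- stack[1]; stack <- stack[-1]
      if (st$maxPath[node] <= thr) {
        g <- g + 1L
        tips <- if (node <= n_tip) node else descTipsOf(tree, node, kids)
        group[tips] <- g
      } else {
        stack <- c(stack, kids[[node]])
      }
    }
    tax[[taxonomyRanks[r + 1]]] <-
      paste0(substr(taxonomyRanks[r + 1], 1, 1), "__", group)
  }
  tax
}

# Descendant tips of a single node (small helper; avoids building the full
# per-node list when only a few nodes are visited).
descTipsOf <- function(tree, node, kids = .childrenList(tree)) {
  n_tip <- ape::Ntip(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    nd <- stack[1]; stack <- stack[-1]
    if (nd <= n_tip) out <- c(out, nd) else stack <- c(stack, kids[[nd]])
  }
  out
}

laplaceCurve <- function(x, mode, scale, amplitude)
  amplitude * exp(-abs(x - mode) / scale)

# Per-branch tag-level harmonic-mean copy-number targets such that the
# expected community ACN equals the configured regime target.
#
# A community in branch B divides its reads between home-matched tags
# (boosted by exp(kappa), copy-number regime B) and cosmopolitan tags
# whose home branches follow the environment composition. Writing
# phi_b = 1/h_b for the tag-level inverse harmonic means, the expected
# inverse ACN in branch B is u*phi_B + (1-u)*sum_b c_b phi_b, with u the
# expected matched read share and c_b the branch composition; setting
# this equal to 1/target_B for every branch gives a linear system.
.solveCopyNumberMixture <- function(cfg, env_branch) {
  targets <- cfg$copyNumberRegimes
  branches <- names(targets)
  cb <- table(factor(env_branch, levels = branches)) / length(env_branch)
  rho <- 1 / length(env_branch)           # P(random tag's home = this env)
  ek <- exp(cfg$kappa)
  match_nonnested <- rho * ek / (rho * ek + 1 - rho)
  f_m <- cfg$nu * rho + (1 - cfg$nu) * match_nonnested
  u <- f_m * ek / (f_m * ek + 1 - f_m)
  A <- (1 - u) * matrix(rep(as.numeric(cb), each = length(branches)),
                        length(branches)) + u * diag(length(branches))
  phi <- solve(A, 1 / targets)
  h <- 1 / phi
  # clamp to what a floor/ceiling mixture of integers in [1, 15] can reach
  setNames(pmin(pmax(h, 1), 15), branches)
}

#' Generate a synthetic world
#'
#' Produces an observation table, sample metadata, tree, taxonomy,
#' copy-number table and a truth record, all deterministic functions of the
#' configuration. See \code{\link{worldConfig}} for the planted structure.
#'
#' @param config a \code{\link{worldConfig}}.
#' @return list with elements \code{table}, \code{metadata}, \code{tree},
#'   \code{taxonomy}, \code{copyNumbers} (data.frame feature_id,
#'   copy_number) and \code{truth} (list of per-tag and per-sample
#'   data.frames).
#' @export
generateWorld <- function(config = worldConfig()) {
  validateWorldConfig(config)
  cfg <- config
  withSeed(cfg$seed, {
    tree <- generateTree(cfg$nTags)
    taxonomy <- taxonomyFromTree(tree)
    tags <- tree$tip.label                     # tag i has global rank i
    envs <- sprintf("env%02d", seq_len(cfg$nEnvironmentsL3))
    env_branch <- setNames(
      empoBranches[((seq_along(envs) - 1L) %% 4L) + 1L], envs)
    env_empo1 <- setNames(ifelse(env_branch %in% c("Animal", "Plant"),
                                 "Host-associated", "Free-living"), envs)
    hosts <- c(Animal = "Mus musculus", Plant = "Zea mays")

    # --- tags: home environment, copy number -------------------------
    # Each genus draws a pool of environments; members draw their home
    # within it, so genus-level environment spread is broad while
    # tip-level spread is as narrow as kappa makes it.
    genus <- taxonomy[tags, "genus"]
    pool_size <- max(2L, ceiling(cfg$genusPoolFraction * length(envs)))
    pools <- lapply(sort(unique(genus)), function(g)
      sample(envs, min(pool_size, length(envs))))
    names(pools) <- sort(unique(genus))
    home <- vapply(seq_along(tags), function(i)
      sample(pools[[genus[i]]], 1), "")
    names(home) <- tags
    # Copy numbers are drawn so the expected COMMUNITY ACN matches the
    # regime target. ACN is a count-weighted harmonic mean, and every
    # community carries a predictable share of cosmopolitan reads from
    # other regimes, so the per-branch tag-level harmonic means are
    # obtained by solving the linear dilution system (in inverse copy
    # numbers) before drawing each tag from a floor/ceiling two-point
    # mixture with that harmonic mean.
    h_branch <- .solveCopyNumberMixture(cfg, env_branch)
    cn_target <- h_branch[env_branch[home]]
    a <- floor(cn_target); b <- a + 1
    w_lo <- ifelse(cn_target == a, 1, (1 / cn_target - 1 / b) / (1 / a - 1 / b))
    copy_number <- as.integer(a + rbinom(length(tags), 1L, 1 - w_lo))

    # --- samples: environment, study, covariate, richness bound ------
    n <- cfg$nSamples
    env_s <- envs[((seq_len(n) - 1L) %% length(envs)) + 1L]
    study_s <- paste0(env_s, "_st",
                      ((seq_len(n) - 1L) %/% length(envs)) %%
                        cfg$nStudiesPerEnv + 1L)
    ph <- rep(NA_real_, n); temp <- rep(NA_real_, n)
    bound <- numeric(n)
    for (i in seq_len(n)) {
      br <- env_branch[env_s[i]]
      if (br == "Non-saline") {
        ph[i] <- runif(1, 2, 12)
        e <- cfg$richnessEnvelope$ph
        bound[i] <- laplaceCurve(ph[i], e[["mode"]], e[["scale"]],
                                 e[["amplitude"]])
      } else if (br == "Saline") {
        temp[i] <- runif(1, -2, 40)
        e <- cfg$richnessEnvelope$temperature_deg_c
        bound[i] <- laplaceCurve(temp[i], e[["mode"]], e[["scale"]],
                                 e[["amplitude"]])
      } else {
        bound[i] <- cfg$hostRichnessCap
      }
    }
    if (all(floor(bound) < 1))
      .stopf("infeasible config: richness bound < 1 everywhere")
    bound <- pmin(pmax(bound, 1), cfg$nTags)
    richness <- vapply(floor(bound), function(b) sample.int(b, 1), 0L)

    # --- presence + counts -------------------------------------------
    m <- matrix(0L, cfg$nTags, n, dimnames = list(tags, NULL))
    dd <- cfg$depthDistribution
    for (i in seq_len(n)) {
      S <- richness[i]
      n_nested <- round(cfg$nu * S)
      incl <- seq_len(n_nested)
      rest <- setdiff(seq_len(cfg$nTags), incl)
      k <- S - n_nested
      if (k > 0) {
        w <- exp(cfg$kappa * (home[rest] == env_s[i]))
        incl <- c(incl, rest[sample.int(length(rest), k, prob = w)])
      }
      if (!cfg$noise) {
        m[incl, i] <- 1L
      } else {
        depth <- max(dd[["min"]],
                     round(exp(rnorm(1, dd[["meanlog"]], dd[["sdlog"]]))))
        ab <- exp(rnorm(length(incl), 0, 1)) *
          exp(cfg$kappa * (home[incl] == env_s[i]))
        m[incl, i] <- rmultinom(1, depth, ab / sum(ab))[, 1]
      }
    }
    sample_ids <- sprintf("S%05d", seq_len(n))
    colnames(m) <- sample_ids

    meta <- SampleMetadata(data.frame(
      study_id = study_s,
      empo_1 = env_empo1[env_s],
      empo_2 = unname(env_branch[env_s]),
      empo_3 = env_s,
      host_scientific_name = ifelse(env_branch[env_s] %in% names(hosts),
                                    hosts[env_branch[env_s]], NA),
      latitude_deg = runif(n, -90, 90),
      ph = ph,
      temperature_deg_c = temp,
      salinity_psu = ifelse(env_branch[env_s] == "Saline",
                            runif(n, 30, 40), NA),
      row.names = sample_ids, stringsAsFactors = FALSE))

    truth <- list(
      tags = data.frame(tag = tags, rank = seq_along(tags),
                        home_env = unname(home),
                        copy_number = copy_number,
                        stringsAsFactors = FALSE),
      samples = data.frame(sample = sample_ids, env = env_s,
                           study = study_s, bound = bound,
                           richness_planted = richness,
                           stringsAsFactors = FALSE))

    list(table = ObservationTable(m), metadata = meta, tree = tree,
         taxonomy = taxonomy,
         copyNumbers = data.frame(feature_id = tags,
                                  copy_number = copy_number,
                                  stringsAsFactors = FALSE),
         truth = truth, config = cfg)
  })
}

#' Write a synthetic world to disk
#'
#' Emits the same flat formats the readers consume, plus the truth record
#' and the flat key-value config.
#'
#' @param world result of \code{\link{generateWorld}}.
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- c(table = file.path(dir, "table.tsv"),
         metadata = file.path(dir, "metadata.tsv"),
         tree = file.path(dir, "tree.nwk"),
         taxonomy = file.path(dir, "taxonomy.tsv"),
         copy_numbers = file.path(dir, "copy_numbers.tsv"),
         truth_tags = file.path(dir, "truth_tags.tsv"),
         truth_samples = file.path(dir, "truth_samples.tsv"),
         config = file.path(dir, "config.txt"))
  writeObservationTable(world$table, p[["table"]])
  writeSampleMetadata(world$metadata, p[["metadata"]])
  ape::write.tree(world$tree, p[["tree"]])
  writeTaxonomyMap(world$taxonomy, p[["taxonomy"]])
  write.table(world$copyNumbers, p[["copy_numbers"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$truth$tags, p[["truth_tags"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(world$truth$samples, p[["truth_samples"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- world$config
  flat <- unlist(cfg[setdiff(names(cfg), "richnessEnvelope")])
  env_flat <- unlist(cfg$richnessEnvelope)
  writeLines(c(paste0(names(flat), " = ", flat),
               paste0("richnessEnvelope.", names(env_flat), " = ", env_flat)),
             p[["config"]])
  p
}
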