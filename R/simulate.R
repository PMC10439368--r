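## Synthetic data: pure-birth trees, Mk locomotor regimes, and
## measurement tables with the covariance structure the analyses assume —
## a shared Brownian log-size factor, correlated Brownian log-shape signal
## with tunable Pagel's lambda, regime-specific mean shifts, and iid
## log-scale measurement noise. Ground truth is recorded for recovery
## tests.

sim_trait_names <- c(
  "skull", "vert", "pelv", "sacr_w", "ESD", "ilium", "uro",
  "fem", "fem_w", "tib", "calc", "foot", "hum", "hum_w", "rad", "hand"
)

# Default regime mean shifts (log scale) for the five locomotor modes,
# echoing the gross contrasts seen in frogs: burrowers and swimmers carry
# wide sacra and robust limbs, jumpers long distal hindlimb segments.
default_delta <- function(k = 5, p = 16, scale = 0.3,
                          traits = sim_trait_names) {
  delta <- matrix(0, k, p, dimnames = list(NULL, traits[seq_len(p)]))
  if (k == 5 && identical(traits[seq_len(p)], sim_trait_names)) {
    rownames(delta) <- locomotor_levels
    set_if <- function(row, cols, val) {
      cols <- intersect(cols, colnames(delta))
      delta[row, cols] <<- val
    }
    set_if("BWH", c("sacr_w", "ESD", "fem_w", "hum_w"), 1)
    set_if("BWH", c("tib", "calc"), -0.5)
    set_if("AQ", c("sacr_w", "ESD", "fem_w", "hum_w", "foot"), 1)
    set_if("AQ", "fem", 0.5)
    set_if("TJ", c("tib", "calc"), 1)
    set_if("TJ", c("ESD", "sacr_w"), -0.7)
    set_if("AJ", c("tib", "hand"), 0.8)
    set_if("AJ", c("fem_w", "ESD"), -0.5)
  } else {
    # generic ladder: regime j shifts trait block j
    for (j in seq_len(k)) {
      cols <- seq.int(1 + ((j - 1) * p) %/% k, (j * p) %/% k)
      delta[j, cols] <- 1
    }
  }
  delta * scale
}

#' Simulation configuration
#'
#' Bundles the generator's parameters with defaults sized to the study
#' conditions the package emulates: 164 tips, 16 log-scale length traits,
#' 5 locomotor regimes, 4 habitats, 3 clades (plus a small 'Neobatrachia'
#' hold-out set), Brownian trait evolution with Pagel's lambda, and iid
#' measurement noise.
#'
#' @param n_tips Number of species (default 164).
#' @param p Number of length traits (default 16, named after the full
#'   variable set with ESD).
#' @param k_modes Number of locomotor regimes (default 5; named after the
#'   locomotor levels when 5).
#' @param q Symmetric Mk transition rate for regime evolution on the
#'   unit-height tree (default 1.5).
#' @param lambda True Pagel's lambda of the shape signal in `[0, 1]`
#'   (default 1).
#' @param Sigma Trait covariance (p × p, PSD). Default
#'   `0.04 * (0.7 I + 0.3 J)`: per-trait Brownian variance 0.04 over the
#'   unit-height tree with mild positive correlation among traits.
#' @param delta Regime mean-shift matrix (k × p, log scale); default
#'   [default_delta()] scaled by `delta_scale`.
#' @param delta_scale Multiplier for the default shift pattern
#'   (default 0.3, i.e. up to ~35% differences in raw measurements).
#' @param sigma2_size Brownian rate of log-size (default 0.25).
#' @param size_offset Mean log geometric-mean size in log-cm
#'   (default 0.3, about 1.35 cm).
#' @param noise_sd Iid log-scale measurement noise sd (default 0.05).
#' @param habitat_confusion Probability that a tip's habitat deviates from
#'   the deterministic locomotor-to-habitat map (default 0.1).
#' @param min_per_state Minimum tips per locomotor regime (default 2, the
#'   smallest class size the discriminant analyses can use).
#' @param n_neo Number of tips labelled 'Neobatrachia' for hold-out clade
#'   prediction (default 10).
#' @param ultrametric Keep the default unit-height ultrametric tree; set
#'   `FALSE` to perturb branch rates (substitutions-per-site mimic).
#' @param seed Root RNG seed (default 1).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_tips = 164, p = 16, k_modes = 5, q = 1.5,
                       lambda = 1, Sigma = NULL, delta = NULL,
                       delta_scale = 0.3, sigma2_size = 0.25,
                       size_offset = 0.3, noise_sd = 0.05,
                       habitat_confusion = 0.1, min_per_state = 2,
                       n_neo = 10, ultrametric = TRUE, seed = 1) {
  traits <- if (p <= length(sim_trait_names)) sim_trait_names[seq_len(p)]
            else c(sim_trait_names, paste0("x", seq_len(p - length(sim_trait_names))))
  if (is.null(Sigma)) {
    Sigma <- 0.04 * (0.7 * diag(p) + 0.3 * matrix(1, p, p))
  }
  stopifnot(nrow(Sigma) == p, ncol(Sigma) == p)
  if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    stop("Sigma must be positive semi-definite")
  }
  if (is.null(delta)) delta <- default_delta(k_modes, p, delta_scale, traits)
  stopifnot(nrow(delta) == k_modes, ncol(delta) == p, all(is.finite(delta)))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (lambda < 0 || lambda > 1) stop("true lambda must lie in [0, 1]")
  structure(
    list(n_tips = n_tips, p = p, traits = traits, k_modes = k_modes, q = q,
         lambda = lambda, Sigma = Sigma, delta = delta,
         sigma2_size = sigma2_size, size_offset = size_offset,
         noise_sd = noise_sd, habitat_confusion = habitat_confusion,
         min_per_state = min_per_state, n_neo = n_neo,
         ultrametric = ultrametric, seed = seed),
    class = "sim_config"
  )
}

#' Simulate a pure-birth tree scaled to unit height
#'
#' @param n_tips Number of tips (≥ 3).
#' @param seed RNG seed.
#' @param ultrametric When `FALSE`, branch lengths receive iid lognormal
#'   rate multipliers (sd 0.3 on the log scale) to mimic
#'   substitutions-per-site trees; the tree is rescaled so the maximum
#'   root-to-tip distance is 1.
#' @return `phylo` with tips `t1..tn` and maximum root-to-tip height 1.
#' @export
simulate_tree <- function(n_tips, seed = 1, ultrametric = TRUE) {
  if (n_tips < 3) stop("n_tips must be at least 3")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  if (!ultrametric) {
    tree$edge.length <- tree$edge.length *
      stats::rlnorm(length(tree$edge.length), 0, 0.3)
  }
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / h
  tree
}

#' Simulate discrete regimes by symmetric Mk evolution
#'
#' Evolves a k-state character from a uniformly drawn root state with
#' symmetric transition rate `q`; redraws (up to 100 times) until every
#' state is present among the tips.
#'
#' @param tree `phylo`.
#' @param k Number of states (≥ 2).
#' @param q Transition rate (> 0).
#' @param seed RNG seed.
#' @param states State labels (default the locomotor levels when k = 5).
#' @param min_per_state Minimum tips per state; draws are repeated until
#'   satisfied (the downstream pooled-covariance analyses need at least 2
#'   members per class).
#' @return Factor of tip states named by tip label.
#' @export
simulate_regimes <- function(tree, k = 5, q = 1.5, seed = 1,
                             states = NULL, min_per_state = 1) {
  if (k < 2) stop("k must be at least 2")
  if (q <= 0) stop("q must be positive")
  if (is.null(states)) {
    states <- if (k == 5) locomotor_levels else paste0("S", seq_len(k))
  }
  set.seed(seed)
  for (try_i in seq_len(100)) {
    root <- sample(states, 1)
    x <- ape::rTraitDisc(tree, model = "ER", k = k, rate = q,
                         states = states, root.value = match(root, states))
    if (length(unique(x)) == k &&
        min(table(factor(x, levels = states))) >= min_per_state) {
      return(factor(stats::setNames(as.character(x), tree$tip.label),
                    levels = states))
    }
  }
  stop("failed to realise all ", k,
       " regimes (>= min_per_state tips each) in 100 draws; increase q")
}

# Sample a matrix-normal draw: row covariance C (n x n), column covariance
# Sigma (p x p). Returns L_C %*% Z %*% t(L_Sigma).
rmatrix_normal <- function(C, Sigma) {
  n <- nrow(C)
  p <- nrow(Sigma)
  Lc <- t(chol_cov(C))
  es <- eigen(Sigma, symmetric = TRUE)
  Ls <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), p)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Lc %*% Z %*% t(Ls)
}

locomotor_habitat_map <- c(
  WH = "terrestrial", BWH = "terrestrial", TJ = "riparian",
  AJ = "arboreal", AQ = "aquatic"
)

# Clade labels from tree structure: the two largest disjoint clades of
# intermediate size become Hyloidea and Ranoidea, the remainder basal,
# from which n_neo tips are relabelled Neobatrachia.
assign_clades <- function(tree, n_neo = 10) {
  n <- length(tree$tip.label)
  clades <- lapply((n + 2):(n + tree$Nnode), function(nd) {
    ape::extract.clade(tree, nd)$tip.label
  })
  sizes <- lengths(clades)
  target1 <- which.min(abs(sizes - 0.40 * n))
  hyl <- clades[[target1]]
  disjoint <- vapply(clades, function(tp) !any(tp %in% hyl), logical(1))
  cand <- which(disjoint)
  if (length(cand) == 0L) stop("tree too unbalanced for clade assignment")
  target2 <- cand[which.min(abs(sizes[cand] - 0.35 * n))]
  ran <- clades[[target2]]
  lab <- stats::setNames(rep("basal", n), tree$tip.label)
  lab[hyl] <- "Hyloidea"
  lab[ran] <- "Ranoidea"
  basal_tips <- names(lab)[lab == "basal"]
  n_neo <- min(n_neo, max(0L, length(basal_tips) - 3L))
  if (n_neo > 0L) {
    lab[sample(basal_tips, n_neo)] <- "Neobatrachia"
  }
  factor(lab, levels = phylo_group_levels)
}

#' Simulate a labelled measurement dataset on a tree
#'
#' Draws the full synthetic dataset: log-measurements are the sum of a
#' Brownian log-size factor (shared across all traits), a matrix-normal
#' shape signal with row covariance `C(lambda)` and column covariance
#' `Sigma`, regime-specific mean shifts `delta`, and iid measurement
#' noise; measurements are the exponentials, so all are strictly
#' positive. Locomotor regimes evolve by symmetric Mk; habitat is a
#' deterministic map of regime with a configurable confusion rate; clades
#' come from the tree's own structure with a 'Neobatrachia' hold-out set;
#' the iliac angle is drawn around regime-specific means (degrees,
#' truncated to (0, 90)) and is not part of the trait covariance.
#'
#' @param config A [sim_config()].
#' @param tree Optional pre-built tree (default: simulated from the
#'   config).
#' @return List of class `synthetic_dataset`: `measurements` (a
#'   `measurement_table`), `tree` (`phylo`), and `truth` (regimes, true
#'   lambda, delta, Sigma, per-tip log-size, seeds).
#' @export
simulate_traits <- function(config = sim_config(), tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(tree)) {
    tree <- simulate_tree(config$n_tips, seed = config$seed,
                          ultrametric = config$ultrametric)
  }
  n <- length(tree$tip.label)
  regimes <- simulate_regimes(tree, k = config$k_modes, q = config$q,
                              seed = config$seed + 1L,
                              min_per_state = config$min_per_state)
  set.seed(config$seed + 2L)
  cov <- brownian_covariance(tree)
  Clam <- lambda_transform(cov, config$lambda)$C
  shape_signal <- rmatrix_normal(Clam, config$Sigma)
  log_size <- if (config$sigma2_size > 0) {
    config$size_offset +
      drop(t(chol_cov(cov$C * config$sigma2_size)) %*% stats::rnorm(n))
  } else {
    rep(config$size_offset, n)
  }
  noise <- matrix(stats::rnorm(n * config$p, sd = config$noise_sd),
                  n, config$p)
  logX <- shape_signal + config$delta[as.integer(regimes), , drop = FALSE] +
    log_size + noise
  colnames(logX) <- config$traits
  rownames(logX) <- tree$tip.label

  # habitat: deterministic map with confusion
  if (config$k_modes == 5) {
    hab <- locomotor_habitat_map[as.character(regimes)]
  } else {
    hab <- habitat_levels[1 + (as.integer(regimes) - 1L) %% 4]
  }
  flip <- stats::runif(n) < config$habitat_confusion
  hab[flip] <- vapply(hab[flip], function(h) {
    sample(setdiff(habitat_levels, h), 1)
  }, character(1))

  clade <- assign_clades(tree, config$n_neo)

  # iliac angle (degrees): regime-specific mean around 9, sd 1.5
  angle_shift <- stats::setNames(rep(0, config$k_modes), levels(regimes))
  if (config$k_modes == 5) {
    angle_shift[c("TJ", "WH")] <- c(-1.5, 1.5)
  }
  theta <- 9 + angle_shift[as.character(regimes)] + stats::rnorm(n, 0, 1.5)
  theta <- pmin(pmax(theta, 1e-3), 90 - 1e-3)

  meas <- data.frame(species_id = tree$tip.label,
                     locomotor_mode = factor(as.character(regimes),
                                             levels = levels(regimes)),
                     habitat = factor(hab, levels = habitat_levels),
                     phylo_group = clade[tree$tip.label],
                     stringsAsFactors = FALSE)
  meas <- cbind(meas, as.data.frame(exp(logX)))
  meas$iliac_angle <- as.numeric(theta)
  rownames(meas) <- meas$species_id
  class(meas) <- c("measurement_table", "data.frame")
  attr(meas, "variable_set") <- c(config$traits, "iliac_angle")

  structure(
    list(measurements = meas, tree = tree,
         truth = list(regimes = regimes, lambda = config$lambda,
                      delta = config$delta, Sigma = config$Sigma,
                      log_size = stats::setNames(log_size, tree$tip.label),
                      seed = config$seed, config = config)),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", nrow(x$measurements), "species,",
      length(x$truth$config$traits), "traits, true lambda =",
      x$truth$lambda, "\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the formats the pipeline consumes: `measurements.csv` (delimited
#' text), `tree.nwk` (Newick) and `truth.json` (ground-truth record), and
#' returns a manifest with md5 checksums. Identical config and seed give
#' byte-identical files.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Manifest: data.frame of file names and checksums (invisibly
#'   the dataset as attribute `dataset`).
#' @export
make_dataset <- function(config = sim_config(), dir) {
  ds <- simulate_traits(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f_meas <- file.path(dir, "measurements.csv")
  f_tree <- file.path(dir, "tree.nwk")
  f_truth <- file.path(dir, "truth.json")
  utils::write.csv(as.data.frame(ds$measurements), f_meas,
                   row.names = FALSE, quote = FALSE)
  write_newick(ds$tree, f_tree)
  truth <- ds$truth
  truth$regimes <- as.character(truth$regimes)
  truth$config <- unclass(truth$config)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             f_truth)
  files <- c(f_meas, f_tree, f_truth)
  manifest <- data.frame(file = basename(files),
                         md5 = as.character(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  attr(manifest, "dataset") <- ds
  manifest
}
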