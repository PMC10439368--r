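# Shared fixture builders: all data are generated in code.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

# A small well-formed measurement table with every full-set column.
toy_measurements <- function(n = 3) {
  set.seed(42)
  vars <- setdiff(measurement_variables("full"), "iliac_angle")
  tab <- data.frame(species_id = paste0("sp", seq_len(n)),
                    locomotor_mode = rep(category_levels()$locomotor_mode,
                                         length.out = n),
                    habitat = rep(category_levels()$habitat, length.out = n),
                    phylo_group = rep(c("basal", "Hyloidea", "Ranoidea"),
                                      length.out = n),
                    stringsAsFactors = FALSE)
  for (v in vars) tab[[v]] <- round(stats::runif(n, 0.5, 5), 3)
  tab$ESD <- round(stats::runif(n, 0.5, 3), 3)
  tab$iliac_angle <- round(stats::runif(n, 5, 15), 2)
  tab
}

# Load a published classification count matrix shipped as plain text.
load_count_fixture <- function(name) {
  path <- system.file("extdata", name, package = "anuromorph")
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$true
  m
}

# Independent slow oracle for the Brownian covariance: per-pair shared
# root-to-MRCA path length computed from explicit root paths.
path_sum_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_edges <- function(i) {
    out <- integer(0)
    while (i != root) {
      out <- c(out, i)
      i <- parent[i]
    }
    out
  }
  paths <- lapply(seq_len(n), path_edges)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}
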