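# Independent oracles and small fixture builders shared across tests.

# Dense multivariate-normal log-density via eigendecomposition: deliberately a
# different linear-algebra route than the package's Cholesky-based likelihood.
oracle_mvn_loglik <- function(z, mu, V) {
  e <- eigen(V, symmetric = TRUE)
  stopifnot(all(e$values > 1e-12))
  w <- crossprod(e$vectors, z - mu)
  -0.5 * (length(z) * log(2 * pi) + sum(log(e$values)) +
            sum(w^2 / e$values))
}

# Explicit element-wise construction of the joint covariance of stacked
# (x, y) species means (written independently of the package internals).
oracle_joint_V <- function(s2x, s2y, sxy, C, dx, dy) {
  n <- nrow(C)
  V <- matrix(NA_real_, 2 * n, 2 * n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      V[i, j] <- s2x * C[i, j] + if (i == j) dx[i] else 0
      V[n + i, n + j] <- s2y * C[i, j] + if (i == j) dy[i] else 0
      V[i, n + j] <- sxy * C[i, j]
      V[n + i, j] <- sxy * C[i, j]
    }
  }
  V
}

# Brute-force clade tabulation for MCC scoring: descendant tip sets found by
# manual recursion over the edge matrix (no ape partition machinery).
oracle_clade_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  desc <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], desc))
  }
  internal <- unique(tree$edge[, 1])
  keys <- vapply(internal, function(nd) {
    paste(sort(desc(nd)), collapse = "|")
  }, "")
  sizes <- vapply(internal, function(nd) length(desc(nd)), 1L)
  unique(keys[sizes > 1L & sizes < ntip])
}

oracle_mcc_scores <- function(sample) {
  per <- lapply(sample, oracle_clade_keys)
  freq <- table(unlist(per, use.names = FALSE)) / length(sample)
  vapply(per, function(k) sum(log(freq[k])), 1.0)
}

# Univariate phylogenetic GLS log-likelihood with known mean profile-fitted,
# evaluated with solve()/determinant() rather than Cholesky.
oracle_pgls_loglik <- function(v, C, s2, d, a) {
  S <- s2 * C + diag(d, nrow(C))
  r <- v - a
  ld <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  -0.5 * (length(v) * log(2 * pi) + ld + drop(t(r) %*% solve(S, r)))
}

# Build abundance_profile objects from a long venom data.frame.
profiles_from_df <- function(df) {
  lapply(split(df, df$record_id), function(s)
    abundance_profile(s$species[1], s$record_id[1], s$source[1], s$method[1],
                      stats::setNames(s$percent_abundance, s$toxin_family)))
}

.index_max_test <- function(index, K) if (index == "shannon") log(K) else 1 - 1 / K

# Minimal species_summary constructor for likelihood tests.
make_summary <- function(species, x, y, svy = rep(0, length(x))) {
  structure(
    list(species = species, x_mean = x, y_mean = y,
         m = rep(1L, length(x)), pooled_within_var_y = 0,
         sampling_var_y = svy, sampling_var_x = rep(0, length(x))),
    class = "species_summary")
}

# One end-to-end synthetic replicate: generate records, push them through the
# compositions stage, fit both models, return fits and the LRT.
roundtrip_fit <- function(scenario, level = "family", n_starts = 2,
                          fit_seed = scenario$seed) {
  tree <- simulate_tree(scenario)
  traits <- simulate_bivariate_traits(tree, scenario)
  rec <- simulate_records(traits, scenario)
  prof <- profiles_from_df(rec$venom)
  cleaned <- clean_venom_profiles(prof)
  filt <- filter_diet(aggregate_diet(rec$diet, level))
  div <- diversity_table(cleaned$profiles,
                         if (level == "family") filt$tables else list(),
                         if (level == "order") filt$tables else list())
  dcol <- paste0("diet_", scenario$index, "_", level)
  vcol <- paste0("venom_", scenario$index)
  rows <- div[!is.na(div[[dcol]]), c("species", dcol, vcol)]
  names(rows) <- c("species", "x", "y")
  tr <- prune_to_taxa(tree, unique(rows$species))
  C <- bm_covariance(tr)
  sm <- suppressWarnings(summarize_replicates(rows))
  full <- suppressWarnings(fit_ives(sm, C, FALSE, n_starts, seed = fit_seed))
  null <- suppressWarnings(fit_ives(sm, C, TRUE, n_starts, seed = fit_seed + 1L))
  list(full = full, null = null,
       lrt = likelihood_ratio_test(full, null),
       n_species = full$n_species)
}
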