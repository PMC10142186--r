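# Synthetic data with known ground truth: ultrametric trees, correlated
# Brownian diversity traits, and compositional venom/diet records whose
# expected diversity matches the trait values.

#' Define a synthetic study scenario
#'
#' Bundles every knob of the generator. Defaults emulate the structure of a
#' multi-study comparative venomics dataset: ~60 species with 1-4 venomic
#' records each, a dated (ultrametric) Yule tree, toxin compositions over 12
#' protein families, diet tables over 15 prey families nested in coarser
#' orders, and a true regression slope of magnitude 0.15 on the index scale.
#' Brownian rates and the intercept are sized so traits stay well inside the
#' attainable index range: clipping at the range boundary is a logged
#' safeguard, not a regular event, because routine clipping would distort the
#' generative regression.
#'
#' @param n_species Number of species (>= 3).
#' @param tree_model "yule" (birth-only dated tree), "star" (all tips at
#'   equal depth; no shared history), or "fixed_newick" (use `newick`).
#' @param birth_rate Yule speciation rate (events per unit time).
#' @param newick Newick string, used when `tree_model = "fixed_newick"`.
#' @param b0,b1 True regression intercept and slope on the index scale.
#' @param sigma2_x Brownian rate of diet diversity (squared index units per
#'   unit branch length).
#' @param sigma2_y_resid Brownian rate of the residual of venom diversity.
#' @param within_sd_y SD of per-record scatter of venom diversity around the
#'   species value (index units).
#' @param replicates_range Integer (min, max) venomic records per species.
#' @param n_toxin_families Number of toxin families per venom composition.
#' @param n_prey_categories Number of prey families available in diets.
#' @param diet_records_range Integer (min, max) total prey records per
#'   species (well-studied species have hundreds of records; the default
#'   range 10-200 mirrors that skew).
#' @param concentration_range Bounds for the solved Dirichlet concentration.
#' @param index Which diversity index the traits live on ("shannon" in nats
#'   or "simpson").
#' @param x_root Trait value of diet diversity at the root.
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the scenario.
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_species = 60,
                               tree_model = c("yule", "star", "fixed_newick"),
                               birth_rate = 1,
                               newick = NULL,
                               b0 = 1.0, b1 = 0.15,
                               sigma2_x = 0.06, sigma2_y_resid = 0.03,
                               within_sd_y = 0.15,
                               replicates_range = c(1L, 4L),
                               n_toxin_families = 12L,
                               n_prey_categories = 15L,
                               diet_records_range = c(10L, 200L),
                               concentration_range = c(1e-4, 1e4),
                               index = c("shannon", "simpson"),
                               x_root = 1.5,
                               seed = 1L) {
  tree_model <- match.arg(tree_model)
  index <- match.arg(index)
  stopifnot(n_species >= 3, birth_rate > 0, sigma2_x > 0, sigma2_y_resid > 0,
            within_sd_y >= 0,
            replicates_range[1] >= 1, diff(replicates_range) >= 0,
            n_toxin_families >= 2, n_prey_categories >= 2,
            diet_records_range[1] >= 1, diff(diet_records_range) >= 0,
            concentration_range[1] > 0, diff(concentration_range) > 0)
  if (tree_model == "fixed_newick" && is.null(newick))
    stop("tree_model = 'fixed_newick' requires a newick string")
  structure(
    list(n_species = as.integer(n_species), tree_model = tree_model,
         birth_rate = birth_rate, newick = newick, b0 = b0, b1 = b1,
         sigma2_x = sigma2_x, sigma2_y_resid = sigma2_y_resid,
         within_sd_y = within_sd_y,
         replicates_range = as.integer(replicates_range),
         n_toxin_families = as.integer(n_toxin_families),
         n_prey_categories = as.integer(n_prey_categories),
         diet_records_range = as.integer(diet_records_range),
         concentration_range = concentration_range,
         index = index, x_root = x_root, seed = as.integer(seed)),
    class = "synthetic_scenario")
}

#' Simulate the scenario's dated phylogeny
#'
#' Yule trees are simulated with a pure-birth process conditioned on the tip
#' count (ultrametric by construction); star trees place every tip at depth 1
#' from the root. Deterministic given the scenario seed.
#'
#' @param scenario A [synthetic_scenario()].
#' @return Rooted ultrametric `phylo` with tips `sp01`, `sp02`, ...
#' @export
simulate_tree <- function(scenario) {
  set.seed(.child_seed(scenario$seed, 1L))
  n <- scenario$n_species
  tree <- switch(scenario$tree_model,
    yule = ape::rphylo(n, birth = scenario$birth_rate, death = 0),
    star = {
      tr <- ape::stree(n, type = "star")
      tr$edge.length <- rep(1, nrow(tr$edge))
      tr
    },
    fixed_newick = ape::read.tree(text = scenario$newick))
  if (ape::Ntip(tree) != n)
    stop("fixed tree has ", ape::Ntip(tree), " tips; scenario expects ", n)
  tree$tip.label <- sprintf("sp%02d", seq_len(n))
  tree
}

#' Simulate correlated species-level diversity traits
#'
#' Exact Brownian simulation by root-to-tip accumulation of independent
#' Gaussian increments per branch: diet diversity x evolves with rate
#' `sigma2_x` from `x_root`; venom diversity is `y = b0 + b1 x + e` with e a
#' Brownian residual of rate `sigma2_y_resid`. Trait values are then clipped
#' into the attainable range of the chosen index given the number of
#' composition categories (clips are counted in attribute `n_clipped`).
#'
#' @param tree Tree from [simulate_tree()].
#' @param scenario The matching scenario.
#' @return data.frame with `species`, `x_true`, `y_true`, and attribute
#'   `n_clipped`.
#' @export
simulate_bivariate_traits <- function(tree, scenario) {
  set.seed(.child_seed(scenario$seed, 2L))
  tree <- stats::reorder(tree, "cladewise")
  n <- ape::Ntip(tree)
  nnode <- n + tree$Nnode
  xv <- numeric(nnode); ev <- numeric(nnode)
  root <- n + 1L
  xv[root] <- scenario$x_root
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1]; child <- tree$edge[i, 2]
    len <- tree$edge.length[i]
    xv[child] <- xv[par] + stats::rnorm(1, 0, sqrt(len * scenario$sigma2_x))
    ev[child] <- ev[par] + stats::rnorm(1, 0, sqrt(len * scenario$sigma2_y_resid))
  }
  x <- xv[seq_len(n)]
  lim_x <- .index_max(scenario$index, scenario$n_prey_categories)
  lim_y <- .index_max(scenario$index, scenario$n_toxin_families)
  margin <- 0.02
  x_cl <- pmin(pmax(x, margin * lim_x), (1 - margin) * lim_x)
  y <- scenario$b0 + scenario$b1 * x_cl + ev[seq_len(n)]
  y_cl <- pmin(pmax(y, margin * lim_y), (1 - margin) * lim_y)
  out <- data.frame(species = tree$tip.label, x_true = x_cl, y_true = y_cl,
                    stringsAsFactors = FALSE)
  attr(out, "n_clipped") <- sum(x != x_cl) + sum(y != y_cl)
  out
}

# Maximum attainable index value with K categories.
.index_max <- function(index, K) {
  if (index == "shannon") log(K) else 1 - 1 / K
}

#' Expected diversity of a symmetric Dirichlet composition
#'
#' Closed forms for a Dirichlet(alpha, ..., alpha) over K categories:
#' expected Shannon index is `digamma(K*alpha + 1) - digamma(alpha + 1)`;
#' expected Gini-Simpson index is `(K - 1)/K * K*alpha / (K*alpha + 1)`.
#' Both increase monotonically with the concentration alpha.
#'
#' @param alpha Symmetric concentration parameter (> 0).
#' @param K Number of categories.
#' @param index "shannon" or "simpson".
#' @return Expected index value.
#' @export
expected_dirichlet_index <- function(alpha, K, index = c("shannon", "simpson")) {
  index <- match.arg(index)
  if (index == "shannon") {
    digamma(K * alpha + 1) - digamma(alpha + 1)
  } else {
    (K - 1) / K * (K * alpha) / (K * alpha + 1)
  }
}

#' Solve the Dirichlet concentration for a target expected diversity
#'
#' Inverts [expected_dirichlet_index()]: analytically for the Gini-Simpson
#' index, by monotone root-finding on the log scale for Shannon. Targets are
#' clamped just inside the attainable open interval (0, max).
#'
#' @inheritParams expected_dirichlet_index
#' @param target Desired expected index value.
#' @param range Concentration bounds for the solve (and the clamp).
#' @return Concentration alpha such that the expected index equals `target`.
#' @export
solve_concentration <- function(target, K, index = c("shannon", "simpson"),
                                range = c(1e-4, 1e4)) {
  index <- match.arg(index)
  lo <- expected_dirichlet_index(range[1], K, index)
  hi <- expected_dirichlet_index(range[2], K, index)
  target <- min(max(target, lo), hi)
  if (index == "simpson") {
    s <- target * K / (K - 1)
    return(min(max(s / (K * (1 - s)), range[1]), range[2]))
  }
  f <- function(la) expected_dirichlet_index(exp(la), K, "shannon") - target
  exp(stats::uniroot(f, log(range), tol = 1e-12)$root)
}

.rdirichlet1 <- function(alpha, K) {
  g <- stats::rgamma(K, shape = alpha, rate = 1)
  if (sum(g) <= 0) {  # extreme underflow at tiny alpha: all mass on one category
    g <- numeric(K); g[sample.int(K, 1)] <- 1
  }
  g / sum(g)
}

# Geometric-series abundance vector p_i proportional to theta^(i-1), with
# theta solved so the chosen index of p equals the target (theta = 1 gives
# the uniform maximum). Used for diet category probabilities.
.geometric_profile <- function(target, K, index) {
  fun <- .diversity_fun(index)
  pvec <- function(theta) {
    w <- theta^(seq_len(K) - 1)
    w / sum(w)
  }
  fmax <- fun(pvec(1))
  if (target >= fmax) return(pvec(1))
  f <- function(theta) fun(pvec(theta)) - target
  eps <- 1e-8
  if (f(eps) > 0) return(pvec(eps))
  theta <- stats::uniroot(f, c(eps, 1), tol = 1e-12)$root
  pvec(theta)
}

#' Simulate venomic and diet record tables from species traits
#'
#' Venom: each species receives `m ~ uniform(replicates_range)` records; each
#' record draws a Dirichlet composition over the toxin families whose
#' concentration is solved so the record's EXPECTED index equals the species
#' value plus Gaussian per-record noise (`within_sd_y`). Within-species
#' variance is therefore real compositional scatter, not additive noise on
#' the index. Diet: a multinomial draw of `N ~ uniform(diet_records_range)`
#' prey records over a geometric abundance profile whose index equals the
#' species diet diversity; prey families are nested two-per-order so both
#' taxonomic levels are populated.
#'
#' @param traits Output of [simulate_bivariate_traits()].
#' @param scenario The matching scenario.
#' @return List with `venom` (long-format venom table), `diet` (diet record
#'   table), and `n_clipped_targets` (record targets clipped into the
#'   attainable range).
#' @export
simulate_records <- function(traits, scenario) {
  set.seed(.child_seed(scenario$seed, 3L))
  K <- scenario$n_toxin_families
  P <- scenario$n_prey_categories
  idx <- scenario$index
  lim_y <- .index_max(idx, K)
  fams <- sprintf("toxfam%02d", seq_len(K))
  prey_f <- sprintf("preyfam%02d", seq_len(P))
  prey_o <- sprintf("preyord%02d", ceiling(seq_len(P) / 2))
  venom <- list(); diet <- list()
  clipped <- 0L
  for (s in seq_len(nrow(traits))) {
    sp <- traits$species[s]
    m <- sample(seq(scenario$replicates_range[1],
                    scenario$replicates_range[2]), 1)
    for (j in seq_len(m)) {
      target <- traits$y_true[s] + stats::rnorm(1, 0, scenario$within_sd_y)
      t_cl <- min(max(target, 0.01 * lim_y), 0.99 * lim_y)
      if (t_cl != target) clipped <- clipped + 1L
      alpha <- solve_concentration(t_cl, K, idx, scenario$concentration_range)
      p <- .rdirichlet1(alpha, K)
      venom[[length(venom) + 1L]] <- data.frame(
        species = sp,
        record_id = sprintf("%s_r%d", sp, j),
        source = sprintf("study_%s_%d", sp, j),
        method = sample(c("proteome", "transcriptome"), 1),
        toxin_family = fams,
        percent_abundance = 100 * p,
        stringsAsFactors = FALSE)
    }
    N <- sample(seq(scenario$diet_records_range[1],
                    scenario$diet_records_range[2]), 1)
    probs <- .geometric_profile(traits$x_true[s], P, idx)
    counts <- as.integer(stats::rmultinom(1, N, probs))
    nz <- counts > 0
    diet[[length(diet) + 1L]] <- data.frame(
      species = sp,
      prey_family = prey_f[nz],
      prey_order = prey_o[nz],
      n_records = counts[nz],
      stringsAsFactors = FALSE)
  }
  list(venom = do.call(rbind, venom),
       diet = do.call(rbind, diet),
       n_clipped_targets = clipped)
}

#' Write a complete synthetic input bundle
#'
#' Simulates tree, traits, and records, and writes them in exactly the
#' formats the pipeline reads: `venom.csv`, `diet.csv`, `tree.nwk`, plus
#' `truth.json` holding the generating parameters and per-species true trait
#' values. Byte-identical for identical scenarios.
#'
#' @param scenario A [synthetic_scenario()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with file `paths`, the `truth` list, and the
#'   in-memory `tree`, `traits`, and `records`.
#' @export
write_scenario_bundle <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(scenario)
  traits <- simulate_bivariate_traits(tree, scenario)
  records <- simulate_records(traits, scenario)
  paths <- list(venom = file.path(outdir, "venom.csv"),
                diet = file.path(outdir, "diet.csv"),
                tree = file.path(outdir, "tree.nwk"),
                truth = file.path(outdir, "truth.json"))
  utils::write.csv(records$venom, paths$venom, row.names = FALSE)
  utils::write.csv(records$diet, paths$diet, row.names = FALSE)
  ape::write.tree(tree, file = paths$tree)
  truth <- list(b0 = scenario$b0, b1 = scenario$b1, index = scenario$index,
                sigma2_x = scenario$sigma2_x,
                sigma2_y_resid = scenario$sigma2_y_resid,
                within_sd_y = scenario$within_sd_y,
                seed = scenario$seed,
                n_clipped_targets = records$n_clipped_targets,
                species = traits$species,
                x_true = traits$x_true, y_true = traits$y_true)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(paths = paths, truth = truth, tree = tree, traits = traits,
                 records = records))
}
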