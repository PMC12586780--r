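#' Parse a Newick tree
#'
#' Thin validated wrapper around [ape::read.tree()]. Branch lengths present
#' in the string are carried but are re-assigned by
#' [assign_grafen_lengths()] before any comparative analysis, since published
#' topologies rarely come with usable divergence times. Trees are interpreted
#' as rooted at their basal node (a basal polytomy is a star tree).
#'
#' @param text Newick string, e.g. `"((A,B),C);"`.
#' @return An [ape] `phylo` object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick string")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  if (length(tr$tip.label) < 2) stop("tree must have >= 2 tips")
  tr
}

#' Write a tree as Newick
#'
#' @param tree A `phylo` object.
#' @return Newick string.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Assign Grafen branch lengths
#'
#' Arbitrary ultrametric branch lengths for topology-only trees: each node's
#' height is proportional to its number of descendant tips minus one, scaled
#' so the root has height 1; a branch's length is the parent height minus the
#' child height. Every root-to-tip path then has length exactly 1. Delegates
#' to [ape::compute.brlen()] with `method = "Grafen", power = 1`.
#'
#' @param tree A `phylo` object (rooted at its basal node).
#' @return The tree with Grafen branch lengths.
#' @export
assign_grafen_lengths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 2) stop("tree must have >= 2 tips")
  ape::compute.brlen(tree, method = "Grafen", power = 1)
}

#' Brownian phylogenetic covariance matrix
#'
#' Expected trait covariance between species under Brownian motion: entry
#' (i, j) is the shared root-to-MRCA path length. With Grafen scaling the
#' diagonal is 1. The result is symmetric positive semi-definite.
#'
#' @param tree An ultrametric `phylo` with branch lengths.
#' @return Species-by-species covariance matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths; run assign_grafen_lengths() first")
  ape::vcv.phylo(tree)
}

#' Species-level heat-transfer table
#'
#' Validated container for per-individual comparative data: body mass and
#' warming/cooling heat transfer coefficients (all strictly positive so they
#' are log10-transformable) with an endothermy flag.
#'
#' @param df Data frame with columns `species`, `individual`, `mass_kg`,
#'   `k_warm`, `k_cool`, `endothermic`.
#' @return A data frame of class `species_k_table`.
#' @export
species_k_table <- function(df) {
  need <- c("species", "individual", "mass_kg", "k_warm", "k_cool",
            "endothermic")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  if (any(df$mass_kg <= 0)) stop("`mass_kg` must be > 0")
  if (any(df$k_warm <= 0) || any(df$k_cool <= 0))
    stop("k values must be > 0 (log10-transformable)")
  if (!is.logical(df$endothermic)) stop("`endothermic` must be logical")
  class(df) <- c("species_k_table", "data.frame")
  df
}

#' Read/write the comparative table CSV
#'
#' Dialect `species,individual,mass_kg,k_warm,k_cool,endothermic`.
#'
#' @param path CSV file path.
#' @return A `species_k_table`.
#' @export
read_species_k_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path)
  df$endothermic <- as.logical(df$endothermic)
  species_k_table(df)
}

#' @rdname read_species_k_table
#' @param table A `species_k_table`.
#' @export
write_species_k_table <- function(table, path) {
  stopifnot(inherits(table, "species_k_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' MCMC settings
#'
#' Defaults are a scaled-down chain (20,000 iterations, 2,000 burn-in, thin
#' 20, 900 retained draws) adequate for this conjugate Gibbs sampler, which
#' mixes far faster than general-purpose samplers; the run lengths used in
#' published comparative analyses (500,000 / 50,000 / 500) are available by
#' passing them here.
#'
#' @param n_iter Total iterations.
#' @param burn Burn-in iterations discarded.
#' @param thin Sampling interval after burn-in.
#' @return A list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 20000, burn = 2000, thin = 20) {
  stopifnot(n_iter > burn, burn >= 0, thin >= 1)
  structure(list(n_iter = as.integer(n_iter), burn = as.integer(burn),
                 thin = as.integer(thin)), class = "mcmc_settings")
}

# design matrix for a formula token
.pmm_design <- function(lmass, endo, formula) {
  switch(formula,
         "mass" = cbind(`(Intercept)` = 1, log10_mass = lmass),
         "mass+endo" = cbind(`(Intercept)` = 1, log10_mass = lmass,
                             endo = as.numeric(endo)),
         "mass*endo" = cbind(`(Intercept)` = 1, log10_mass = lmass,
                             endo = as.numeric(endo),
                             `log10_mass:endo` = lmass * as.numeric(endo)),
         stop("unknown formula: ", formula))
}

# conditional Gaussian deviance given fixed and random effects
.cond_deviance <- function(y, X, sp, beta, u, s, sig2e) {
  mu <- as.vector(X %*% beta) + u[sp] + s[sp]
  e <- y - mu
  length(y) * (log(2 * pi) + log(sig2e)) + sum(e^2) / sig2e
}

#' Fit the phylogenetic mixed model
#'
#' Bayesian Gaussian mixed model for a log10-transformed heat transfer
#' response against log10 body mass, endothermy and their interaction:
#' `y = X beta + u + s + e`, with a Brownian phylogenetic species effect
#' `u ~ N(0, sigma2_p A)` (A from [phylo_covariance()] of the Grafen-scaled
#' tree), an i.i.d. species effect `s ~ N(0, sigma2_s I)` absorbing
#' intraspecific replicate structure, and residual
#' `e ~ N(0, sigma2_e I)`. Fitted by a blocked Gibbs sampler with conjugate
#' updates: diffuse normal priors on the coefficients (variance 1e8) and
#' inverse-gamma(0.001, 0.001) priors on the three variances. Deterministic
#' under `seed`.
#'
#' @param table A [species_k_table()]; every species must be a tip of `tree`.
#' @param tree A `phylo`; Grafen branch lengths are assigned internally.
#' @param response `"k_warm"`, `"k_cool"` or `"ratio"` (`k_warm/k_cool`,
#'   computed per individual before the log10 transform).
#' @param formula `"mass"`, `"mass+endo"` or `"mass*endo"`.
#' @param mcmc An [mcmc_settings()] list.
#' @param seed Integer seed.
#' @param prior List with `beta_var`, `ig_shape`, `ig_rate`.
#' @return A list of class `phylo_mixed_fit` with posterior `draws` (matrices
#'   `beta`, `u`, `s`, `sigma2`, vector `deviance`), `dic`, `data`,
#'   `response`, `formula`, `settings` and `seed`.
#' @export
fit_phylo_mixed <- function(table, tree,
                            response = c("k_warm", "k_cool", "ratio"),
                            formula = c("mass*endo", "mass+endo", "mass"),
                            mcmc = mcmc_settings(), seed = 1L,
                            prior = list(beta_var = 1e8, ig_shape = 0.001,
                                         ig_rate = 0.001)) {
  stopifnot(inherits(table, "species_k_table"), inherits(tree, "phylo"))
  response <- match.arg(response)
  formula <- match.arg(formula)

  if (!all(table$species %in% tree$tip.label))
    stop("species missing from tree: ",
         paste(setdiff(unique(table$species), tree$tip.label),
               collapse = ", "))

  yk <- switch(response, k_warm = table$k_warm, k_cool = table$k_cool,
               ratio = table$k_warm / table$k_cool)
  y <- log10(yk)
  lmass <- log10(table$mass_kg)

  endo_by_sp <- tapply(table$endothermic, table$species, unique)
  if (formula != "mass") {
    n_endo <- sum(unlist(endo_by_sp))
    n_ecto <- length(endo_by_sp) - n_endo
    if (n_endo == 0 || n_ecto == 0)
      stop("singular design: one endothermy group is empty")
    if (formula == "mass*endo" && (n_endo < 2 || n_ecto < 2))
      stop("interaction formula needs >= 2 species per endothermy group")
  }
  X <- .pmm_design(lmass, table$endothermic, formula)

  species <- sort(unique(table$species))
  sp <- match(table$species, species)
  A <- phylo_covariance(assign_grafen_lengths(tree))[species, species]
  Ainv <- solve(A)

  set.seed(as.integer(seed))
  raw <- gibbs_pmm_cpp(y, X, sp - 1L, Ainv,
                       mcmc$n_iter, mcmc$burn, mcmc$thin,
                       prior$beta_var, prior$ig_shape, prior$ig_rate)
  colnames(raw$beta) <- colnames(X)
  colnames(raw$u) <- colnames(raw$s) <- species
  colnames(raw$sigma2) <- c("phylo", "species", "resid")

  fit <- structure(list(draws = raw,
                        data = list(y = y, X = X, sp = sp,
                                    species = species,
                                    endothermic = table$endothermic),
                        response = response, formula = formula,
                        settings = mcmc, seed = as.integer(seed),
                        prior = prior),
                   class = "phylo_mixed_fit")
  fit$dic <- compute_dic(fit)$dic
  fit
}

#' Deviance information criterion of a fitted model
#'
#' Conditional-deviance DIC: `DIC = Dbar + pD`, `pD = Dbar - D(theta_bar)`,
#' where the deviance is minus twice the Gaussian log-likelihood conditional
#' on the random-effect draws and `theta_bar` collects posterior means of the
#' coefficients, random effects and residual variance.
#'
#' @param fit A `phylo_mixed_fit` with >= 100 retained draws.
#' @return A list with `dic`, `pD`, `Dbar`, `Dhat`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "phylo_mixed_fit"))
  d <- fit$draws
  if (length(d$deviance) < 100) stop("need >= 100 retained draws")
  if (any(!is.finite(d$deviance))) stop("non-finite deviance in draws")
  Dbar <- mean(d$deviance)
  Dhat <- .cond_deviance(fit$data$y, fit$data$X, fit$data$sp,
                         colMeans(d$beta), colMeans(d$u), colMeans(d$s),
                         mean(d$sigma2[, "resid"]))
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Posterior summary of fixed effects
#'
#' @param object A `phylo_mixed_fit`.
#' @param ... Unused.
#' @return Data frame with posterior mean, SD and central 95% credible
#'   interval per coefficient, plus variance components and DIC as
#'   attributes.
#' @export
summary.phylo_mixed_fit <- function(object, ...) {
  B <- object$draws$beta
  out <- data.frame(
    coef = colnames(B),
    mean = colMeans(B),
    sd = apply(B, 2, stats::sd),
    lower95 = apply(B, 2, quantile, 0.025),
    upper95 = apply(B, 2, quantile, 0.975),
    row.names = NULL)
  attr(out, "sigma2_mean") <- colMeans(object$draws$sigma2)
  attr(out, "dic") <- object$dic
  out
}

#' @export
print.phylo_mixed_fit <- function(x, ...) {
  cat(sprintf("Phylogenetic mixed model: log10(%s) ~ %s\n",
              x$response, x$formula))
  cat(sprintf("  %d retained draws, DIC = %.2f\n",
              nrow(x$draws$beta), x$dic))
  print(summary(x))
  invisible(x)
}

#' Rank candidate models by DIC
#'
#' @param fits List of `phylo_mixed_fit` objects for the same response and
#'   data (checked against the response vector).
#' @return Data frame with `formula`, `response`, `dic`, `delta_dic`, sorted
#'   ascending by DIC.
#' @export
rank_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  y0 <- fits[[1]]$data$y
  for (f in fits) {
    if (!isTRUE(all.equal(f$data$y, y0)))
      stop("fits are not on identical data")
  }
  out <- data.frame(
    formula = vapply(fits, function(f) f$formula, character(1)),
    response = vapply(fits, function(f) f$response, character(1)),
    dic = vapply(fits, function(f) as.numeric(f$dic), numeric(1)))
  out <- out[order(out$dic), , drop = FALSE]
  out$delta_dic <- out$dic - out$dic[1]
  rownames(out) <- NULL
  out
}

#' Allometric regression lines per endothermy group
#'
#' Extracts the group-specific intercept and slope (log10 scale) from the
#' posterior means of a fitted model: for the interaction formula the
#' endothermic line is `(b0 + b_endo, b_mass + b_int)` and the ectothermic
#' line `(b0, b_mass)`.
#'
#' @param fit A `phylo_mixed_fit`.
#' @return Data frame with columns `group` (`"endothermic"`,
#'   `"ectothermic"`), `intercept` (log10 k at 1 kg) and `slope`.
#' @export
allometry_lines <- function(fit) {
  b <- colMeans(fit$draws$beta)
  b0 <- b[["(Intercept)"]]
  bm <- b[["log10_mass"]]
  be <- if ("endo" %in% names(b)) b[["endo"]] else 0
  bi <- if ("log10_mass:endo" %in% names(b)) b[["log10_mass:endo"]] else 0
  data.frame(group = c("endothermic", "ectothermic"),
             intercept = c(b0 + be, b0),
             slope = c(bm + bi, bm))
}

#' Predict a heat transfer coefficient from an allometric line
#'
#' `k = 10^intercept * mass^slope` for the requested endothermy group.
#'
#' @param lines Data frame with columns `group`, `intercept` (log10 scale),
#'   `slope` (as returned by [allometry_lines()] or [published_allometry()]).
#' @param mass Body mass (kg), > 0; vectorised.
#' @param endothermic Logical: which group's line to evaluate.
#' @return Predicted coefficient(s), 1/min (dimensionless for the ratio).
#' @export
predict_k_at_mass <- function(lines, mass, endothermic) {
  stopifnot(all(mass > 0), is.logical(endothermic))
  g <- if (endothermic) "endothermic" else "ectothermic"
  row <- lines[lines$group == g, , drop = FALSE]
  if (nrow(row) != 1) stop("no unique line for group ", g)
  10^row$intercept * mass^row$slope
}

#' Endotherm-ectotherm contrast at a reference mass
#'
#' Fold-difference between the group regression lines at `mass`, in the
#' direction in which the difference is reported: endothermic over
#' ectothermic for the warming coefficient and the warming:cooling ratio
#' (endotherms warm faster and modulate more), ectothermic over endothermic
#' for the cooling coefficient (endotherms cool slower).
#'
#' @param lines Data frame of group lines for one response (columns `group`,
#'   `intercept`, `slope`).
#' @param mass Reference body mass (kg).
#' @param response `"k_warm"`, `"k_cool"` or `"ratio"`; sets the direction.
#' @return Fold-difference (> 1 when the groups differ in the reported
#'   direction).
#' @export
contrast_at_mass <- function(lines, mass,
                             response = c("k_warm", "k_cool", "ratio")) {
  response <- match.arg(response)
  k_endo <- predict_k_at_mass(lines, mass, TRUE)
  k_ecto <- predict_k_at_mass(lines, mass, FALSE)
  if (response == "k_cool") k_ecto / k_endo else k_endo / k_ecto
}

#' Published allometric regression lines
#'
#' The fitted group-level allometries reported for warming and cooling heat
#' transfer coefficients across 25 fish species (e.g. warming coefficient
#' `0.11 * mass^-0.21` for endotherms, `0.16 * mass^-0.50` for ectotherms),
#' shipped as a plain-text table. Intercepts are returned on the log10 scale
#' for use with [predict_k_at_mass()] and [contrast_at_mass()].
#'
#' @return Data frame with columns `response`, `group`, `coefficient`,
#'   `exponent`, `intercept` (= `log10(coefficient)`), `slope`
#'   (= `exponent`).
#' @export
published_allometry <- function() {
  path <- system.file("extdata", "published_allometry.csv",
                      package = "thermofin", mustWork = TRUE)
  df <- read.csv(path)
  df$intercept <- log10(df$coefficient)
  df$slope <- df$exponent
  df
}

#' Published heat-exchange model estimates for tagged mako sharks
#'
#' Constant- and variable-model parameter estimates (with MAE and AIC)
#' reported for four tagged shortfin mako sharks, shipped as a plain-text
#' table for reference and arithmetic checks.
#'
#' @return Data frame with columns `shark`, `model`, `k`, `k_warm`,
#'   `k_cool`, `ratio`, `tm_dot`, `mae`, `aic`.
#' @export
published_heatfit <- function() {
  path <- system.file("extdata", "published_heatfit.csv",
                      package = "thermofin", mustWork = TRUE)
  read.csv(path)
}
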