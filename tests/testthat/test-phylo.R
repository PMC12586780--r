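test_that("newick parsing validates topology and round-trips", {
  tr <- parse_newick("((A,B),C);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2)

  star <- parse_newick("(A,B,C);")
  expect_equal(star$Nnode, 1)

  back <- parse_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(tr, back, use.edge.length = FALSE))

  expect_error(parse_newick("((A,A),B);"), "duplicate")
  expect_error(parse_newick("((A,B,C);"), "malformed")
})

test_that("Grafen branch lengths make every root-to-tip path unit length", {
  two <- assign_grafen_lengths(parse_newick("(A,B);"))
  expect_equal(sort(two$edge.length), c(1, 1))

  tr <- assign_grafen_lengths(parse_newick("((A,B),C);"))
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(depths[1:3], rep(1, 3))  # ultrametric, scaled to 1
  # heights 2 (root) and 1 (cherry), scaled by 1/2
  lens <- sort(tr$edge.length)
  expect_equal(lens, c(0.5, 0.5, 0.5, 1.0))

  bal <- assign_grafen_lengths(parse_newick("((A,B),(C,D));"))
  expect_equal(ape::node.depth.edgelength(bal)[1:4], rep(1, 4))

  # property: unit root-to-tip depth on random topologies
  for (seed in 1:10) {
    set.seed(seed)
    rt <- ape::rtree(sample(4:20, 1))
    g <- assign_grafen_lengths(rt)
    nt <- length(g$tip.label)
    expect_equal(ape::node.depth.edgelength(g)[seq_len(nt)], rep(1, nt),
                 tolerance = 1e-12)
  }
})

test_that("Brownian covariance encodes shared ancestry", {
  star <- assign_grafen_lengths(parse_newick("(A,B,C,D);"))
  expect_equal(phylo_covariance(star), diag(4),
               ignore_attr = TRUE)

  V <- phylo_covariance(assign_grafen_lengths(parse_newick("((A,B),C);")))
  expect_equal(unname(diag(V)), rep(1, 3))
  expect_equal(V["A", "B"], 0.5)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["B", "C"], 0)

  for (seed in 1:5) {
    set.seed(seed)
    g <- assign_grafen_lengths(ape::rtree(12))
    ev <- eigen(phylo_covariance(g), symmetric = TRUE, only.values = TRUE)
    expect_gt(min(ev$values), -1e-10)
  }

  expect_error(phylo_covariance(parse_newick("(A,B,C);") |>
                                  (\(t) { t$edge.length <- NULL; t })()),
               "branch lengths")
})

test_that("star-tree posterior means match the ordinary least-squares oracle", {
  n_sp <- 50
  star <- ape::stree(n_sp, type = "star")
  star$tip.label <- sprintf("s%02d", seq_len(n_sp))
  endo <- setNames(rep(FALSE, n_sp), star$tip.label)
  endo[1:25] <- TRUE
  tab <- simulate_comparative_dataset(
    star, endo,
    coef_warm = list(endo = c(-1, -0.3), ecto = c(-1, -0.3)),
    sd_phylo = 0, sd_species = 0, sd_resid = 0.15,
    individuals_per_species = 1, seed = 8)
  fit <- fit_phylo_mixed(tab, star, response = "k_warm", formula = "mass",
                         mcmc = mcmc_settings(20000, 2000, 20), seed = 8)
  ols <- coef(lm(log10(tab$k_warm) ~ log10(tab$mass_kg)))
  B <- fit$draws$beta
  for (j in 1:2) {
    batches <- matrix(B[seq_len(900), j], nrow = 30)
    mcse <- sd(colMeans(batches)) / sqrt(30)
    expect_lt(abs(mean(B[, j]) - ols[j]), 3 * mcse + 1e-4)
  }
})

test_that("exact linear data concentrate the slope posterior at the truth", {
  ct <- make_comp_tree(n_tips = 12, n_endo = 4)
  tab <- simulate_comparative_dataset(
    ct$tree, ct$endo,
    coef_warm = list(endo = c(-0.8, -0.4), ecto = c(-0.8, -0.4)),
    sd_phylo = 0, sd_species = 0, sd_resid = 0,
    individuals_per_species = 2, seed = 5)
  fit <- fit_phylo_mixed(tab, ct$tree, "k_warm", "mass",
                         mcmc = quick_mcmc(), seed = 5)
  sm <- summary(fit)
  slope <- sm[sm$coef == "log10_mass", ]
  expect_equal(slope$mean, -0.4, tolerance = 1e-3)
  expect_lt(slope$sd, 0.01)
})

test_that("the sampler recovers generating slopes and flags its settings", {
  ct <- make_comp_tree()
  tab <- simulate_comparative_dataset(ct$tree, ct$endo, seed = 17)
  fit <- fit_phylo_mixed(tab, ct$tree, "k_warm", "mass*endo",
                         mcmc = quick_mcmc(), seed = 17)
  expect_equal(nrow(fit$draws$beta),
               (quick_mcmc()$n_iter - quick_mcmc()$burn) / quick_mcmc()$thin)
  B <- fit$draws$beta
  ecto_ci <- quantile(B[, "log10_mass"], c(0.025, 0.975))
  endo_draw <- B[, "log10_mass"] + B[, "log10_mass:endo"]
  endo_ci <- quantile(endo_draw, c(0.025, 0.975))
  expect_true(ecto_ci[1] <= -0.50 && -0.50 <= ecto_ci[2])
  expect_true(endo_ci[1] <= -0.21 && -0.21 <= endo_ci[2])
  expect_true(all(fit$draws$sigma2 >= 0))

  # deterministic under seed
  fit2 <- fit_phylo_mixed(tab, ct$tree, "k_warm", "mass*endo",
                          mcmc = quick_mcmc(), seed = 17)
  expect_identical(fit$draws$beta, fit2$draws$beta)

  onegrp <- tab
  onegrp$endothermic <- FALSE
  expect_error(fit_phylo_mixed(species_k_table(onegrp), ct$tree, "k_warm",
                               "mass*endo", mcmc = quick_mcmc()),
               "singular|group")
})

test_that("conditional deviance is invariant to species relabeling", {
  ct <- make_comp_tree(n_tips = 8, n_endo = 3)
  tab <- simulate_comparative_dataset(ct$tree, ct$endo, seed = 9)
  fit <- fit_phylo_mixed(tab, ct$tree, "k_warm", "mass",
                         mcmc = quick_mcmc(), seed = 9)
  d <- compute_dic(fit)
  # permute species indices together with the random-effect vectors
  perm <- sample(length(fit$data$species))
  fit2 <- fit
  fit2$data$sp <- match(fit$data$sp, perm)
  fit2$draws$u <- fit$draws$u[, perm, drop = FALSE]
  fit2$draws$s <- fit$draws$s[, perm, drop = FALSE]
  d2 <- compute_dic(fit2)
  expect_equal(d2$Dhat, d$Dhat, tolerance = 1e-12)
  expect_equal(d2$dic, d$dic, tolerance = 1e-12)
})

test_that("DIC reduces to the plug-in deviance for a point-mass posterior", {
  ct <- make_comp_tree(n_tips = 8, n_endo = 3)
  tab <- simulate_comparative_dataset(ct$tree, ct$endo, seed = 11)
  fit <- fit_phylo_mixed(tab, ct$tree, "k_warm", "mass",
                         mcmc = quick_mcmc(), seed = 11)
  pm <- fit
  m <- nrow(fit$draws$beta)
  rep_row <- function(M) matrix(M[1, ], m, ncol(M), byrow = TRUE,
                                dimnames = dimnames(M))
  pm$draws$beta <- rep_row(fit$draws$beta)
  pm$draws$u <- rep_row(fit$draws$u)
  pm$draws$s <- rep_row(fit$draws$s)
  pm$draws$sigma2 <- rep_row(fit$draws$sigma2)
  dev1 <- length(fit$data$y) *
    (log(2 * pi) + log(pm$draws$sigma2[1, "resid"])) +
    sum((fit$data$y - as.vector(fit$data$X %*% pm$draws$beta[1, ]) -
           pm$draws$u[1, fit$data$sp] - pm$draws$s[1, fit$data$sp])^2) /
    pm$draws$sigma2[1, "resid"]
  pm$draws$deviance <- rep(dev1, m)
  d <- compute_dic(pm)
  expect_equal(d$pD, 0, tolerance = 1e-9)
  expect_equal(d$dic, d$Dhat, tolerance = 1e-9)
})

test_that("model ranking orders by DIC with deltas against the best", {
  y0 <- rnorm(10)
  stub <- function(dic, formula) {
    structure(list(dic = dic, formula = formula, response = "ratio",
                   data = list(y = y0)),
              class = "phylo_mixed_fit")
  }
  one <- rank_models(list(stub(-47.24, "mass*endo")))
  expect_equal(one$delta_dic, 0)

  three <- rank_models(list(stub(-34.78, "mass+endo"),
                            stub(-47.24, "mass*endo"),
                            stub(-34.41, "mass")))
  expect_equal(three$formula, c("mass*endo", "mass+endo", "mass"))
  expect_equal(three$delta_dic, c(0, 12.46, 12.83))

  # permuting the input order leaves the ranking unchanged
  perm <- rank_models(list(stub(-34.41, "mass"), stub(-47.24, "mass*endo"),
                           stub(-34.78, "mass+endo")))
  expect_equal(perm, three)

  bad <- stub(-10, "mass")
  bad$data$y <- rnorm(10)
  expect_error(rank_models(list(stub(-47.24, "mass*endo"), bad)),
               "identical data")
})

test_that("allometric prediction and contrasts follow the reported directions", {
  lines <- data.frame(group = c("endothermic", "ectothermic"),
                      intercept = c(log10(0.11), log10(0.16)),
                      slope = c(-0.21, -0.50))
  # at 1 kg the prediction is the multiplicative intercept itself
  expect_equal(predict_k_at_mass(lines, 1, TRUE), 0.11)
  expect_equal(predict_k_at_mass(lines, 1, FALSE), 0.16)
  expect_equal(predict_k_at_mass(lines, 140, TRUE),
               0.11 * 140^-0.21)
  expect_equal(signif(contrast_at_mass(lines, 140, "k_warm"), 2), 2.9)

  cool <- data.frame(group = c("endothermic", "ectothermic"),
                     intercept = c(log10(0.11), log10(0.11)),
                     slope = c(-0.68, -0.54))
  expect_equal(signif(contrast_at_mass(cool, 140, "k_cool"), 2), 2.0)
  expect_error(predict_k_at_mass(lines[0, ], 140, TRUE), "no unique line")
})
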