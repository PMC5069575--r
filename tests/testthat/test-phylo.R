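test_that("branch-length log transform is monotone, order-preserving and non-idempotent", {
  tt <- generate_tree_and_traits(20, seed = 301)$tree
  tr1 <- transform_branch_lengths(tt)
  expect_true(all(order(tt$edge.length) == order(tr1$edge.length)))
  # equal branches stay equal
  eq <- tt
  eq$edge.length <- rep(1, length(eq$edge.length))
  teq <- transform_branch_lengths(eq)
  expect_equal(length(unique(round(teq$edge.length, 12))), 1)
  # applying it twice is not the same as once
  tr2 <- transform_branch_lengths(tr1)
  expect_false(isTRUE(all.equal(tr1$edge.length, tr2$edge.length)))
  neg <- tt
  neg$edge.length[1] <- -0.1
  expect_error(transform_branch_lengths(neg), "negative")
})

test_that("independent contrasts match the closed forms and the pruning fixture", {
  # two tips: contrast (3 - 1)/sqrt(1 + 1)
  t2 <- ape::read.tree(text = "(A:1,B:1);")
  c2 <- independent_contrasts(t2, c(A = 3, B = 1))
  expect_equal(c2$contrast, 2 / sqrt(2), tolerance = 1e-12)

  # three tips, hand-worked through the pruning recursion:
  # node(A,B): contrast (1-3)/sqrt(2), ancestor value 2, branch 1 + 1/2
  # root: contrast (2-6)/sqrt(1.5 + 2)
  t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  c3 <- independent_contrasts(t3, c(A = 1, B = 3, C = 6))
  expect_equal(sort(abs(c3$contrast)),
               sort(abs(c(-2 / sqrt(2), -4 / sqrt(3.5)))), tolerance = 1e-12)
  expect_equal(nrow(c3), 2)
})

test_that("contrast count is n - 1 and contrasts are equivariant under affine maps", {
  sim <- generate_tree_and_traits(25, seed = 302)
  cs <- independent_contrasts(sim$tree, sim$traits)
  expect_equal(nrow(cs), 24)
  # a * x + c scales contrasts by a (constant drops out)
  cs2 <- independent_contrasts(sim$tree, 3.5 * sim$traits + 11)
  expect_equal(cs2$contrast, 3.5 * cs$contrast, tolerance = 1e-10)
  # constant trait: all contrasts zero
  cs0 <- independent_contrasts(sim$tree,
                               setNames(rep(2, 25), names(sim$traits)))
  expect_equal(cs0$contrast, rep(0, 24))
  expect_error(independent_contrasts(sim$tree, sim$traits[-1]),
               names(sim$traits)[1])
})

test_that("contrasts agree with the reference pruning implementation", {
  for (seed in c(311, 312, 313)) {
    sim <- generate_tree_and_traits(30, seed = seed)
    mine <- independent_contrasts(sim$tree, sim$traits)
    ref <- ape::pic(sim$traits[sim$tree$tip.label], sim$tree)
    expect_equal(sort(abs(mine$contrast)), sort(abs(unname(ref))),
                 tolerance = 1e-10)
  }
})

test_that("Blomberg's K is near 1 for Brownian traits and matches the reference implementation", {
  sim <- generate_tree_and_traits(50, seed = 320)
  ks <- numeric(100)
  tree <- sim$tree
  for (i in 1:100) {
    x <- simulate_bm_seeded(tree, 1, 400 + i)
    ks[i] <- blomberg_k(tree, x)
  }
  expect_gt(mean(ks), 0.8)
  expect_lt(mean(ks), 1.25)
  x <- simulate_bm_seeded(tree, 1, 999)
  k_ref <- unname(phytools::phylosig(tree, x, method = "K"))
  expect_equal(blomberg_k(tree, x), as.numeric(k_ref), tolerance = 1e-8)
})

test_that("K is exactly the no-signal baseline on a star and orders random below Brownian on a pectinate tree", {
  # independent equidistant tips: observed and expected MSE ratios cancel
  star <- ape::stree(40, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  set.seed(330)
  x_star <- setNames(rnorm(40), star$tip.label)
  expect_equal(blomberg_k(star, x_star), 1, tolerance = 1e-10)
  # pectinate tree: tip-shuffled traits lose the signal BM traits carry
  # (single draws of K are noisy, so compare replicate means)
  pect <- ape::stree(40, type = "left")
  pect$edge.length <- rep(1, nrow(pect$edge))
  k_bm <- k_rand <- numeric(20)
  for (i in 1:20) {
    x_bm <- simulate_bm_seeded(pect, 1, 332 + i)
    set.seed(400 + i)
    x_rand <- setNames(sample(x_bm), names(x_bm))
    k_bm[i] <- blomberg_k(pect, x_bm)
    k_rand[i] <- blomberg_k(pect, x_rand)
  }
  expect_lt(mean(k_rand), mean(k_bm))
  expect_error(blomberg_k(star, setNames(rep(1, 40), star$tip.label)),
               "zero variance")
})

test_that("Pagel's lambda separates Brownian from permuted traits and matches the reference", {
  sim <- generate_tree_and_traits(50, seed = 340)
  fit_bm <- pagel_lambda(sim$tree, sim$traits)
  expect_gt(fit_bm$lambda, 0.8)
  set.seed(341)
  perm <- setNames(sample(sim$traits), names(sim$traits))
  fit_perm <- pagel_lambda(sim$tree, perm)
  expect_lt(fit_perm$lambda, 0.2)
  # lambda = 0 reduces to independent tips with common mean and variance
  x <- sim$traits
  n <- length(x)
  v <- diag(stomalloc:::tree_vcv(sim$tree))
  w <- 1 / v
  mu <- sum(w * x) / sum(w)
  sig2 <- sum((x - mu)^2 / v) / n
  ll0_direct <- -0.5 * (n * log(2 * pi * sig2) + sum(log(v)) + n)
  expect_equal(fit_bm$logLik0, ll0_direct, tolerance = 1e-8)
  ref <- phytools::phylosig(sim$tree, sim$traits, method = "lambda")
  expect_equal(fit_bm$lambda, ref$lambda, tolerance = 0.01)
  expect_equal(fit_bm$logLik, ref$logL, tolerance = 1e-3)
})

test_that("PIC allometry recovers an exact inverse relationship and is robust to sign conventions", {
  sim <- generate_tree_and_traits(30, seed = 350)
  z <- sim$traits / stats::sd(sim$traits)
  traits <- tibble::tibble(
    species = names(z), clade = "angiosperm", subclade = NA_character_,
    amphistomatous = FALSE, d_s = 10^(8 + z), a_gc = 10^(-9.5 - z),
    a_max = NA_real_
  )
  f <- pic_allometry(sim$tree, traits, d_s, a_gc)
  expect_equal(f$exponent, -1, tolerance = 1e-10)
  expect_true(f$through_origin)
  expect_equal(nrow(f$contrasts), 29)
})

test_that("PIC slope is consistent with the species-level SMA for correlated Brownian traits", {
  sim <- generate_tree_and_traits(60, seed = 360)
  z <- sim$traits
  set.seed(361)
  noise <- simulate_bm_seeded(sim$tree, 0.05, 362)
  traits <- tibble::tibble(
    species = names(z), clade = "angiosperm", subclade = NA_character_,
    amphistomatous = FALSE, d_s = 10^(8 + z),
    a_gc = 10^(-9.5 - 1.1 * z + noise), a_max = NA_real_
  )
  f_pic <- pic_allometry(sim$tree, traits, d_s, a_gc)
  f_sma <- sma_fit(traits, d_s, a_gc)
  expect_gte(f_pic$exponent, f_sma$ci_exponent[1] - 0.15)
  expect_lte(f_pic$exponent, f_sma$ci_exponent[2] + 0.15)
  # phylogenetic signal summary runs on the same inputs
  sig <- phylo_signal(sim$tree, traits, c("d_s", "a_gc"))
  expect_equal(nrow(sig), 2)
  expect_true(all(sig$pagel_lambda >= 0))
})
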