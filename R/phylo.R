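#' Logarithmic branch-length transformation
#'
#' Rescales branch lengths as b -> log10(b / b_floor + 1), the
#' transformation used to remove the relationship between branch lengths
#' and the magnitude of standardized contrasts before computing them. The
#' additive 1 keeps zero-length branches at zero; `b_floor` sets the scale
#' below which branches are effectively collapsed.
#'
#' @param tree An `ape::phylo` tree with branch lengths >= 0.
#' @param b_floor Scale floor; default 1e-6 of the tree depth.
#' @return A new `phylo` tree with transformed branch lengths; the input
#'   is untouched. Strictly monotone in the original lengths, and not
#'   idempotent (applying it twice is not the same as once).
#' @export
transform_branch_lengths <- function(tree, b_floor = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length < 0)) abort("negative branch lengths")
  if (is.null(b_floor)) {
    depth <- max(ape::node.depth.edgelength(tree))
    b_floor <- 1e-6 * depth
  }
  out <- tree
  out$edge.length <- log10(tree$edge.length / b_floor + 1)
  out
}

# Resolve polytomies to zero-length branches (deterministic order).
resolve_tree <- function(tree) {
  if (!ape::is.binary(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  tree
}

#' Phylogenetically independent contrasts (Felsenstein pruning)
#'
#' Computes standardized independent contrasts of a tip trait by the
#' pruning algorithm: at each internal node joining daughters i, j with
#' (extended) branch lengths b_i, b_j, the contrast is
#' (x_i - x_j) / sqrt(b_i + b_j); the ancestral value is the
#' 1/b-weighted average of the daughters and the ancestral branch is
#' extended by b_i b_j / (b_i + b_j). Polytomies are resolved to
#' zero-length branches first.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param x Named numeric vector of tip values; names must match the tip
#'   labels exactly (missing tips are an error, listing the offenders).
#' @return A tibble with one row per internal node: `node`, `contrast`,
#'   `node_depth` (height above the tips on the branch-length scale).
#'   Exactly n_tips - 1 rows on a bifurcating tree.
#' @export
independent_contrasts <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"))
  tree <- resolve_tree(tree)
  ntip <- length(tree$tip.label)
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0("missing trait values for tips: ",
                 paste(missing_tips, collapse = ", ")))
  }
  x <- x[tree$tip.label]

  nnode <- tree$Nnode
  val <- c(unname(x), rep(NA_real_, nnode))
  blen <- numeric(ntip + nnode)
  blen[tree$edge[, 2]] <- tree$edge.length
  children <- split(tree$edge[, 2], tree$edge[, 1])

  contrasts <- numeric(0)
  nodes <- integer(0)
  depths <- numeric(0)
  node_height <- ape::node.depth.edgelength(tree)
  node_height <- max(node_height) - node_height  # height above tips

  # postorder over internal nodes
  order_nodes <- unique(tree$edge[ape::postorder(tree), 1])
  for (nd in order_nodes) {
    kids <- children[[as.character(nd)]]
    stopifnot(length(kids) == 2)
    i <- kids[1]; j <- kids[2]
    bi <- blen[i]; bj <- blen[j]
    contrasts <- c(contrasts, (val[i] - val[j]) / sqrt(bi + bj))
    nodes <- c(nodes, nd)
    depths <- c(depths, node_height[nd])
    wi <- 1 / bi; wj <- 1 / bj
    if (!is.finite(wi) && !is.finite(wj)) {
      val[nd] <- (val[i] + val[j]) / 2
    } else if (!is.finite(wi)) {
      val[nd] <- val[i]
    } else if (!is.finite(wj)) {
      val[nd] <- val[j]
    } else {
      val[nd] <- (wi * val[i] + wj * val[j]) / (wi + wj)
    }
    blen[nd] <- blen[nd] + bi * bj / (bi + bj)
  }
  tibble::tibble(node = nodes, contrast = contrasts, node_depth = depths)
}

# Brownian-motion covariance matrix (shared branch length) of the tips.
tree_vcv <- function(tree) {
  ape::vcv(tree)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' K compares the ratio of the trait's mean squared error around the
#' phylogenetic (GLS) mean to its phylogenetically corrected mean squared
#' error, against the expectation of that ratio under Brownian motion on
#' the same tree. K near 1 indicates Brownian-like signal; K near 0, none.
#'
#' @param tree An `ape::phylo` tree.
#' @param x Named numeric tip trait vector.
#' @return The K statistic (scalar).
#' @export
blomberg_k <- function(tree, x) {
  tree <- resolve_tree(tree)
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0("missing trait values for tips: ",
                 paste(missing_tips, collapse = ", ")))
  }
  x <- x[tree$tip.label]
  if (sd(x) == 0) abort("trait has zero variance: K undefined")
  n <- length(x)
  V <- tree_vcv(tree)
  Vi <- solve(V)
  one <- rep(1, n)
  a_hat <- as.numeric((one %*% Vi %*% x) / (one %*% Vi %*% one))
  dx <- x - a_hat
  mse0 <- sum(dx^2) / (n - 1)
  mse <- as.numeric(dx %*% Vi %*% dx) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

#' Pagel's lambda estimate of phylogenetic signal
#'
#' Maximises the Gaussian Brownian-motion log-likelihood of the tip data
#' under the lambda-transformed covariance
#' V(lambda) = lambda * V_offdiag + diag(V), with the mean and rate
#' profiled out analytically, over lambda in \[0, lambda_max\] by 1-D
#' bounded optimisation (tolerance 1e-6). At lambda = 0 the model reduces
#' to independent tips with a common mean and variance.
#'
#' @param tree An `ape::phylo` tree.
#' @param x Named numeric tip trait vector.
#' @param lambda_max Upper search bound; default is the largest value
#'   keeping V(lambda) positive-definite for an ultrametric tree
#'   (max diagonal / max off-diagonal shared branch length), capped only
#'   by that geometry.
#' @return A list: `lambda` (the ML estimate), `logLik`, `logLik0`
#'   (log-likelihood at lambda = 0), `convergence`.
#' @export
pagel_lambda <- function(tree, x, lambda_max = NULL) {
  tree <- resolve_tree(tree)
  missing_tips <- setdiff(tree$tip.label, names(x))
  if (length(missing_tips) > 0) {
    abort(paste0("missing trait values for tips: ",
                 paste(missing_tips, collapse = ", ")))
  }
  x <- x[tree$tip.label]
  if (sd(x) == 0) abort("trait has zero variance")
  n <- length(x)
  V <- tree_vcv(tree)
  dV <- diag(V)
  offV <- V - diag(dV)
  if (is.null(lambda_max)) {
    lambda_max <- max(dV) / max(offV[offV > 0])
    lambda_max <- min(lambda_max, 1.5)
  }

  loglik <- function(lambda) {
    Vl <- lambda * offV + diag(dV)
    ch <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Vi_x <- backsolve(ch, forwardsolve(t(ch), x))
    Vi_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
    mu <- sum(Vi_x) / sum(Vi_1)
    dx <- x - mu
    Vi_dx <- backsolve(ch, forwardsolve(t(ch), dx))
    sig2 <- sum(dx * Vi_dx) / n
    -0.5 * (n * log(2 * pi * sig2) + logdet + n)
  }

  opt <- optimize(loglik, interval = c(0, lambda_max),
                  maximum = TRUE, tol = 1e-6)
  ll0 <- loglik(0)
  # optimize never visits the exact endpoints; snap if they dominate
  cand <- c(opt$maximum, 0, lambda_max)
  lls <- c(opt$objective, ll0, loglik(lambda_max))
  best <- which.max(lls)
  if (!is.finite(lls[best])) abort("lambda likelihood optimisation failed")
  list(lambda = cand[best], logLik = lls[best], logLik0 = ll0,
       convergence = TRUE)
}

#' Allometry between independent contrasts of two log10 traits
#'
#' Computes PICs of log10-transformed traits for the species shared by the
#' trait table and the tree, and fits a through-origin SMA to them — the
#' phylogenetically controlled analogue of the species-level allometric
#' fit. Contrasts are positivized on x (y following), which leaves the
#' through-origin slope magnitude unchanged.
#'
#' @param tree An `ape::phylo` tree whose tip labels match `traits$species`.
#' @param traits Species-average tibble.
#' @param x,y Bare column names of the positive traits.
#' @param transform_branches Apply [transform_branch_lengths()] first.
#' @return An `sma_fit` (through origin) with an added `contrasts` element
#'   (tibble of the paired contrasts).
#' @export
pic_allometry <- function(tree, traits, x, y, transform_branches = TRUE) {
  x_name <- rlang::as_name(rlang::enquo(x))
  y_name <- rlang::as_name(rlang::enquo(y))
  cc <- traits[!is.na(traits[[x_name]]) & !is.na(traits[[y_name]]), ]
  shared <- intersect(tree$tip.label, cc$species)
  if (length(shared) < 3) abort("fewer than 3 species shared by tree and traits")
  dropped <- setdiff(tree$tip.label, shared)
  tr <- if (length(dropped) > 0) ape::drop.tip(tree, dropped) else tree
  if (transform_branches) tr <- transform_branch_lengths(tr)
  cc <- cc[match(tr$tip.label, cc$species), ]
  xv <- setNames(log10(cc[[x_name]]), cc$species)
  yv <- setNames(log10(cc[[y_name]]), cc$species)
  px <- independent_contrasts(tr, xv)
  py <- independent_contrasts(tr, yv)
  flip <- ifelse(px$contrast < 0, -1, 1)
  cx <- px$contrast * flip
  cy <- py$contrast * flip
  fit <- sma_fit_through_origin(cx, cy)
  fit$x_name <- paste0("pic(log10 ", x_name, ")")
  fit$y_name <- paste0("pic(log10 ", y_name, ")")
  fit$contrasts <- tibble::tibble(node = px$node, x_contrast = cx,
                                  y_contrast = cy)
  fit
}

#' Phylogenetic-signal summary for a set of traits
#'
#' Blomberg's K and Pagel's lambda for each (log10-transformed) trait
#' column, on the species shared with the tree.
#'
#' @param tree An `ape::phylo` tree.
#' @param traits Species-average tibble.
#' @param trait_cols Character vector of positive trait columns.
#' @return A tibble: `trait`, `n`, `blomberg_k`, `pagel_lambda`, `logLik`.
#' @export
phylo_signal <- function(tree, traits,
                         trait_cols = c("d_s", "a_gc")) {
  purrr::map_dfr(trait_cols, function(tc) {
    cc <- traits[!is.na(traits[[tc]]), ]
    shared <- intersect(tree$tip.label, cc$species)
    tr <- ape::drop.tip(tree, setdiff(tree$tip.label, shared))
    cc <- cc[match(tr$tip.label, cc$species), ]
    v <- setNames(log10(cc[[tc]]), cc$species)
    pl <- pagel_lambda(tr, v)
    tibble::tibble(trait = tc, n = length(v),
                   blomberg_k = blomberg_k(tr, v),
                   pagel_lambda = pl$lambda, logLik = pl$logLik)
  })
}
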