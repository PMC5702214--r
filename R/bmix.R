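# Clonal inference: mixture of multivariate Bernoulli distributions fit by
# expectation-maximization on the binary cell-by-mutation matrix.
#
# Model: cell i belongs to latent cluster z_i with P(z_i = k) = pi_k, and
# given z_i = k its calls are independent Bernoulli,
#   P(x_i | z_i = k) = prod_j theta[k,j]^x_ij (1 - theta[k,j])^(1 - x_ij).
# theta[k,j] is the probability that assay j is called present in a cell of
# cluster k. M-step estimates of theta are smoothed with Jeffreys
# pseudocounts (a = b = 0.5) so parameters stay off {0,1} and log-likelihoods
# stay finite.

#' Estimate the number of cell clusters by hierarchical clustering
#'
#' Agglomerative clustering (average linkage) on Hamming distances between
#' the rows of the binary matrix; candidate cuts at K = 2..`k_max` are scored
#' by mean silhouette width and the best cut wins. K = 1 is returned when no
#' cut achieves a mean silhouette of at least `min_silhouette` (no real
#' cluster structure) or when the matrix has fewer than two distinct rows.
#'
#' @param X binary matrix (cells x assays) or a `genotype_matrix`.
#' @param k_max largest K considered (default 8).
#' @param min_silhouette floor below which K = 1 is declared (default 0.1).
#' @return list with `K`, `silhouette` (named vector of mean widths per
#'   candidate K) and `hclust` (the dendrogram, reusable as an EM
#'   initialization).
#' @export
estimate_k <- function(X, k_max = 8L, min_silhouette = 0.1) {
  if (inherits(X, "genotype_matrix")) X <- X$X
  n <- nrow(X)
  if (n < 1L) stop("empty matrix", call. = FALSE)
  if (n == 1L) {
    return(list(K = 1L, silhouette = numeric(), hclust = NULL))
  }
  d <- dist(X, method = "manhattan")  # = Hamming counts for 0/1 rows
  if (max(d) == 0) {
    return(list(K = 1L, silhouette = numeric(), hclust = NULL))
  }
  hc <- hclust(d, method = "average")
  ks <- seq(2L, min(k_max, n - 1L))
  sil <- vapply(ks, function(k) {
    lab <- cutree(hc, k)
    if (length(unique(lab)) < 2L) return(NA_real_)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  if (all(is.na(sil)) || max(sil, na.rm = TRUE) < min_silhouette) {
    K <- 1L
  } else {
    K <- ks[which.max(sil)]
  }
  list(K = K, silhouette = sil, hclust = hc)
}

# one EM run from an initial responsibility matrix; returns params + trace.
# With pseudocounts (a, b) the M-step is the posterior mode under a
# Beta(a + 1, b + 1) prior on each theta[k, j], so the quantity EM increases
# monotonically is the log-posterior (log-likelihood plus the Beta log-prior,
# up to a constant); that objective drives convergence and the trace.
run_em <- function(X, W, gamma, a, b, tol, max_iter) {
  n <- nrow(X)
  WX <- W * X
  W1mX <- W * (1 - X)
  prior_term <- function(theta) sum(a * log(theta) + b * log1p(-theta))
  trace <- numeric(0)
  obj_prev <- -Inf
  pi_k <- theta <- NULL
  ll <- NA_real_
  for (it in seq_len(max_iter)) {
    # M-step from current responsibilities
    pi_k <- colSums(gamma) / n
    theta <- (crossprod(gamma, WX) + a) / (crossprod(gamma, W) + a + b)
    # E-step / objective with the new parameters
    L <- WX %*% t(log(theta)) + W1mX %*% t(log1p(-theta))
    L <- sweep(L, 2L, log(pmax(pi_k, 1e-300)), `+`)
    rls <- logsumexp_rows(L)
    ll <- sum(rls)
    obj <- ll + prior_term(theta)
    trace <- c(trace, obj)
    gamma <- exp(L - rls)
    if (is.finite(obj_prev) &&
        abs(obj - obj_prev) < tol * (abs(obj_prev) + .Machine$double.eps)) {
      break
    }
    obj_prev <- obj
  }
  list(pi = pi_k, theta = theta, gamma = gamma, loglik = ll,
       objective = trace[length(trace)], loglik_trace = trace,
       n_iter = length(trace), converged = length(trace) < max_iter)
}

#' Fit a mixture of multivariate Bernoulli distributions by EM
#'
#' Clusters the rows (cells) of a binary genotype matrix into `K` latent
#' populations. Each restart draws random initial responsibilities from a
#' flat Dirichlet; one additional deterministic restart is initialized from
#' the average-linkage hierarchical-clustering cut at `K` (the same procedure
#' used by [estimate_k()]), anchoring the fit while the random restarts guard
#' against local optima. The best restart by final log-likelihood is kept.
#'
#' By default every matrix entry participates (missing data were already
#' encoded as 0 when the matrix was built); with `use_mask = TRUE`, entries
#' marked in the mask are skipped in both the E-step products and the M-step
#' sums, so no-data entries carry no evidence.
#'
#' @param X binary matrix (cells x assays) or a `genotype_matrix`.
#' @param K number of clusters (>= 1, <= number of cells).
#' @param n_restarts random restarts (default 20) in addition to the
#'   hierarchical-clustering initialization.
#' @param tol convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @param max_iter iteration cap per restart (default 500).
#' @param seed optional RNG seed; identical seed gives identical output.
#' @param smooth pseudocounts `c(a, b)` added to the M-step beta counts
#'   (default Jeffreys, `c(0.5, 0.5)`).
#' @param mask optional 0/1 matrix (1 = no data); taken from a
#'   `genotype_matrix` automatically.
#' @param use_mask skip masked entries instead of treating them as 0
#'   (default FALSE, matching a plain binary matrix with no missing state).
#' @param init optional list of additional initializations added to the
#'   restart pool: each element is either a length-n vector of hard cluster
#'   labels in 1..K or an n x K responsibility matrix. EM ascends
#'   monotonically from each, so supplying a candidate partition guarantees
#'   the fit scores at least as well as that partition.
#' @return object of class `bmix`: `K`, `pi` (mixing weights), `theta`
#'   (K x J presence probabilities), `gamma` (n x K responsibilities),
#'   `cluster` (argmax labels), `loglik` (observed-data log-likelihood),
#'   `objective` (the EM objective: with smoothing pseudocounts `(a, b)` the
#'   M-step is the posterior mode under a Beta(a+1, b+1) prior on each
#'   theta entry, and EM monotonically increases the corresponding
#'   log-posterior; with `smooth = c(0, 0)` it equals `loglik`),
#'   `loglik_trace` (per-iteration objective of the best restart;
#'   non-decreasing), `n_iter`, `converged`.
#' @seealso [estimate_k()], [derive_mutation_clusters()],
#'   [flag_doublet_clusters()]
#' @export
bmix <- function(X, K, n_restarts = 20L, tol = 1e-6, max_iter = 500L,
                 seed = NULL, smooth = c(0.5, 0.5), mask = NULL,
                 use_mask = FALSE, init = NULL) {
  if (inherits(X, "genotype_matrix")) {
    if (is.null(mask)) mask <- X$mask
    X <- X$X
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  J <- ncol(X)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > n) stop("K (", K, ") exceeds the number of cells (", n, ")",
                  call. = FALSE)
  if (!all(X %in% c(0, 1))) stop("matrix entries must be 0/1", call. = FALSE)
  a <- smooth[1]; b <- smooth[2]
  W <- if (use_mask && !is.null(mask)) 1 - as.matrix(mask) else
    matrix(1, n, J)
  if (!is.null(seed)) set.seed(seed)

  if (K == 1L) {
    # closed form: smoothed column means, no iteration needed
    theta <- matrix((colSums(W * X) + a) / (colSums(W) + a + b), nrow = 1L)
    ll <- sum((W * X) %*% t(log(theta)) + (W * (1 - X)) %*% t(log1p(-theta)))
    obj <- ll + sum(a * log(theta) + b * log1p(-theta))
    fit <- list(pi = 1, theta = theta, gamma = matrix(1, n, 1L),
                loglik = ll, objective = obj, loglik_trace = obj,
                n_iter = 1L, converged = TRUE)
  } else {
    if (K > 1L && max(dist(X, method = "manhattan")) == 0) {
      warning("all cells identical: K > 1 is degenerate; extra clusters ",
              "will empty out (pi -> 0)", call. = FALSE)
    }
    inits <- vector("list", n_restarts + 1L)
    for (r in seq_len(n_restarts)) {
      g <- matrix(stats::rgamma(n * K, shape = 1), n, K)
      inits[[r]] <- g / rowSums(g)
    }
    # deterministic anchor from the hierarchical-clustering cut
    hcut <- tryCatch(cutree(hclust(dist(X, method = "manhattan"), "average"), K),
                     error = function(e) sample.int(K, n, replace = TRUE))
    gh <- matrix(0.05 / max(K - 1, 1), n, K)
    gh[cbind(seq_len(n), hcut)] <- 0.95
    inits[[n_restarts + 1L]] <- gh / rowSums(gh)
    for (ini in init) {
      if (is.matrix(ini)) {
        stopifnot(nrow(ini) == n, ncol(ini) == K)
        g <- ini / rowSums(ini)
      } else {
        stopifnot(length(ini) == n, all(ini %in% seq_len(K)))
        g <- matrix(0, n, K)
        g[cbind(seq_len(n), ini)] <- 1
      }
      inits[[length(inits) + 1L]] <- g
    }
    runs <- lapply(inits, function(g)
      run_em(X, W, g, a = a, b = b, tol = tol, max_iter = max_iter))
    fit <- runs[[which.max(vapply(runs, `[[`, numeric(1), "objective"))]]
  }

  dimnames(fit$theta) <- list(paste0("cluster", seq_len(K)),
                              colnames(X) %||% paste0("assay", seq_len(J)))
  dimnames(fit$gamma) <- list(rownames(X), rownames(fit$theta))
  structure(c(fit, list(
    K = K, n = n, J = J,
    cluster = max.col(fit$gamma, ties.method = "first"),
    use_mask = use_mask, smooth = smooth, seed = seed,
    call = match.call()
  )), class = "bmix")
}

#' @export
print.bmix <- function(x, ...) {
  cat(sprintf("Bernoulli mixture model: %d clusters, %d cells x %d assays\n",
              x$K, x$n, x$J))
  cat(sprintf("log-likelihood %.3f after %d EM iterations (%s)\n",
              x$loglik, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  cat("mixing weights:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("cluster sizes: ",
      paste(tabulate(x$cluster, x$K), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.bmix <- function(object, present_threshold = 0.5, ...) {
  mc <- derive_mutation_clusters(object, present_threshold)
  structure(list(fit = object,
                 sizes = tabulate(object$cluster, object$K),
                 mutation_clusters = table(mc$label),
                 mean_max_gamma = mean(apply(object$gamma, 1L, max))),
            class = "summary.bmix")
}

#' @export
print.summary.bmix <- function(x, ...) {
  print(x$fit)
  cat(sprintf("mean max responsibility: %.3f\n", x$mean_max_gamma))
  cat("mutation clusters:\n")
  print(x$mutation_clusters)
  invisible(x)
}

#' @export
coef.bmix <- function(object, ...) {
  list(pi = object$pi, theta = object$theta)
}

#' @export
logLik.bmix <- function(object, ...) {
  structure(object$loglik,
            df = (object$K - 1) + object$K * object$J,
            nobs = object$n, class = "logLik")
}

#' Posterior cluster membership for new cells
#'
#' @param object fitted `bmix`.
#' @param newdata binary matrix of cells x assays (same assays, same order);
#'   defaults to the responsibilities of the training cells.
#' @param type `"class"` for argmax labels, `"posterior"` for the full
#'   responsibility matrix.
#' @param ... unused.
#' @export
predict.bmix <- function(object, newdata = NULL,
                         type = c("class", "posterior"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    gamma <- object$gamma
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != object$J) {
      stop("newdata must have ", object$J, " assay columns", call. = FALSE)
    }
    L <- newdata %*% t(log(object$theta)) +
      (1 - newdata) %*% t(log1p(-object$theta))
    L <- sweep(L, 2L, log(pmax(object$pi, 1e-300)), `+`)
    gamma <- exp(L - logsumexp_rows(L))
  }
  if (type == "posterior") gamma else max.col(gamma, ties.method = "first")
}

#' Draw cells from a fitted Bernoulli mixture
#'
#' @param object fitted `bmix`.
#' @param nsim number of cells to draw.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return list with `X` (nsim x J binary matrix) and `cluster` (true
#'   component of each draw).
#' @export
simulate.bmix <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(object$K, nsim, replace = TRUE, prob = object$pi)
  X <- matrix(rbinom(nsim * object$J, 1L,
                     object$theta[z, , drop = FALSE]),
              nrow = nsim)
  colnames(X) <- colnames(object$theta)
  list(X = X, cluster = z)
}

#' @export
fitted.bmix <- function(object, ...) {
  object$gamma %*% object$theta
}

#' @export
#' @importFrom graphics par image axis
#' @importFrom grDevices gray.colors
plot.bmix <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b", pch = 16,
       xlab = "EM iteration", ylab = "log-likelihood",
       main = "EM convergence", ...)
  ord <- order(x$cluster)
  image(t(x$gamma[ord, , drop = FALSE]), axes = FALSE,
        col = gray.colors(32, start = 1, end = 0),
        xlab = "cluster", ylab = "cells (sorted by assignment)",
        main = "responsibilities")
  axis(1, at = seq(0, 1, length.out = x$K), labels = seq_len(x$K))
  invisible(x)
}

#' Group assays into mutation clusters by their presence pattern
#'
#' Each assay's per-cluster presence probabilities are thresholded at
#' `present_threshold` (inclusive), giving a 0/1 pattern over clusters;
#' assays with identical patterns form a mutation cluster. The all-ones
#' pattern is the ancestral cluster (present in every clone); the all-zeros
#' pattern collects poor-performing assays (present in no cluster); a
#' single-1 pattern is clone-specific.
#'
#' @param model fitted `bmix`.
#' @param present_threshold probability cut (default 0.5).
#' @param exclude optional cluster indices to drop from the pattern (e.g.
#'   flagged doublet clusters, so patterns reflect clones only).
#' @return data.frame `assay_id`, `pattern` (e.g. `"110"`), `label`
#'   (`ancestral`, `poor`, `clone-<k>-specific`, or `shared-...`).
#' @export
derive_mutation_clusters <- function(model, present_threshold = 0.5,
                                     exclude = NULL) {
  keep <- setdiff(seq_len(model$K), exclude)
  P <- (model$theta[keep, , drop = FALSE] >= present_threshold) * 1L
  pattern <- apply(P, 2L, paste, collapse = "")
  label <- vapply(seq_len(ncol(P)), function(j) {
    p <- P[, j]
    if (all(p == 1L)) return("ancestral")
    if (all(p == 0L)) return("poor")
    if (sum(p) == 1L) return(sprintf("clone-%d-specific", keep[which(p == 1L)]))
    sprintf("shared-%s", paste(keep[p == 1L], collapse = "+"))
  }, character(1))
  data.frame(assay_id = colnames(model$theta) %||%
               paste0("assay", seq_len(ncol(model$theta))),
             pattern = pattern, label = label, stringsAsFactors = FALSE)
}

#' Flag clusters that look like doublets of two clones
#'
#' A chamber holding two cells yields the union of two clones' mutation
#' profiles. A cluster is flagged as a doublet cluster when its presence
#' profile is well approximated (mean absolute deviation below `tolerance`)
#' by the elementwise maximum of two other clusters' profiles, and that union
#' approximates it strictly better than any single other cluster does (so a
#' duplicate of an existing clone is never flagged — that situation belongs
#' to model selection, not doublet detection).
#'
#' @param model fitted `bmix` with K >= 3 (a doublet must be expressible as
#'   the union of two other clusters).
#' @param tolerance mean absolute deviation bound (default 0.15).
#' @return integer vector of flagged cluster indices (possibly empty).
#' @export
flag_doublet_clusters <- function(model, tolerance = 0.15) {
  K <- model$K
  if (K < 3L) return(integer(0))
  theta <- model$theta
  flagged <- integer(0)
  for (d in seq_len(K)) {
    others <- setdiff(seq_len(K), d)
    dev_single <- min(vapply(others, function(e)
      mean(abs(theta[d, ] - theta[e, ])), numeric(1)))
    pairs <- combn(others, 2L)
    dev_union <- min(vapply(seq_len(ncol(pairs)), function(p) {
      ab <- pairs[, p]
      mean(abs(theta[d, ] - pmax(theta[ab[1], ], theta[ab[2], ])))
    }, numeric(1)))
    if (dev_union < tolerance && dev_union < dev_single) {
      flagged <- c(flagged, d)
    }
  }
  flagged
}
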