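# Pan/core/new-gene rarefaction over genome orderings, Heaps'-law and
# exponential-decay fits, and open/closed pan-genome classification.

# all permutations of 1..n (used only when n! is small)
perms_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_all(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Pan/core/new-gene rarefaction curves
#'
#' For each genome ordering, `pan(x)` is the number of families present in
#' the first `x` genomes, `core(x)` the number present in *all* of the first
#' `x`, and `new(x) = pan(x) - pan(x-1)` (with `new(1) = pan(1)`). Orderings
#' are uniform random permutations; when all `G!` orderings are few
#' (`G <= 5`, or `G! <= n_perm`) they are enumerated exhaustively instead, so
#' the means are exact.
#'
#' @param pa Presence/absence tibble (first column `family_id`).
#' @param n_perm Number of random genome orderings.
#' @param seed Integer seed for the orderings.
#' @return An object of class `rarefaction_curves`: list with `summary`
#'   (tibble `x`, `pan_mean`, `core_mean`, `new_mean`), per-permutation
#'   integer matrices `pan`, `core`, `new` (one row per ordering), `G`,
#'   `n_permutations`, `exhaustive`, `seed`.
#' @examples
#' pa <- tibble::tibble(family_id = c("F1", "F2", "F3"),
#'                      g1 = c(1L, 1L, 0L), g2 = c(1L, 0L, 1L),
#'                      g3 = c(1L, 0L, 1L))
#' rarefy(pa)$summary
#' @export
rarefy <- function(pa, n_perm = 100L, seed = 1L) {
  if (nrow(pa) == 0) pf_stop("empty presence/absence matrix", "input")
  if (n_perm < 1) pf_stop("n_perm must be >= 1", "input")
  m <- pa_as_matrix(pa) > 0
  G <- ncol(m)
  if (G < 2) pf_stop("need at least 2 genomes", "input")
  exhaustive <- G <= 5 || factorial(G) <= n_perm
  orderings <- if (exhaustive) {
    perms_all(G)
  } else {
    set.seed(as.integer(seed))
    t(replicate(n_perm, sample.int(G)))
  }
  P <- nrow(orderings)
  pan <- core <- new <- matrix(0L, P, G)
  for (p in seq_len(P)) {
    ord <- orderings[p, ]
    seen <- m[, ord[1]]
    inall <- m[, ord[1]]
    pan[p, 1] <- sum(seen); core[p, 1] <- sum(inall)
    for (x in 2:G) {
      seen <- seen | m[, ord[x]]
      inall <- inall & m[, ord[x]]
      pan[p, x] <- sum(seen); core[p, x] <- sum(inall)
    }
    new[p, ] <- c(pan[p, 1], diff(pan[p, ]))
  }
  structure(list(
    summary = tibble(x = seq_len(G), pan_mean = colMeans(pan),
                     core_mean = colMeans(core), new_mean = colMeans(new)),
    pan = pan, core = core, new = new, G = G, n_permutations = P,
    exhaustive = exhaustive, seed = as.integer(seed)),
    class = "rarefaction_curves")
}

#' @export
print.rarefaction_curves <- function(x, ...) {
  cat(sprintf("<rarefaction_curves> G = %d over %d ordering(s)%s\n",
              x$G, x$n_permutations, if (x$exhaustive) " (exhaustive)" else ""))
  print(x$summary, n = 5)
  invisible(x)
}

#' @rdname rarefy
#' @param x A `rarefaction_curves` object.
#' @param ... Unused.
#' @method tidy rarefaction_curves
#' @export
tidy.rarefaction_curves <- function(x, ...) {
  tidyr::pivot_longer(x$summary, -"x", names_to = "curve",
                      values_to = "families") %>%
    mutate(curve = sub("_mean$", "", .data$curve))
}

#' Rarefaction curve plot
#'
#' @param object A `rarefaction_curves` object.
#' @param ... Unused.
#' @method autoplot rarefaction_curves
#' @export
autoplot.rarefaction_curves <- function(object, ...) {
  ggplot(tidy(object), aes(.data$x, .data$families, colour = .data$curve)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "genomes sampled", y = "gene families")
}

# shared nonlinear least-squares driver with jittered restarts
nls_restarts <- function(formula, data, start, lower, upper, n_restart = 5L,
                         seed_jitter = 42L) {
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                     maxiter = 500)
  try1 <- function(st) tryCatch(
    minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                      upper = upper, control = ctrl),
    error = function(e) NULL)
  fit <- try1(start)
  if (is.null(fit)) {
    set.seed(seed_jitter)
    for (r in seq_len(n_restart)) {
      st <- lapply(start, function(v) v * stats::runif(1, 0.5, 1.5) +
                     stats::runif(1, -1, 1))
      names(st) <- names(start)
      st <- purrr::map2(st, names(st),
                        function(v, nm) min(max(v, lower[nm]), upper[nm]))
      fit <- try1(st)
      if (!is.null(fit)) break
    }
  }
  if (is.null(fit))
    pf_stop("nonlinear fit failed to converge after bounded restarts",
            "convergence")
  fit
}

r_squared <- function(y, yhat) 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)

#' Fit Heaps' law to a pan-genome accumulation curve
#'
#' Nonlinear least squares of `y = kappa * x^gamma + b`. In pan-genomics a
#' fitted exponent `gamma > 0` diagnoses an open pan-genome (the pan-genome
#' keeps growing as genomes are added).
#'
#' @param x Genome counts (>= 4 points).
#' @param y Pan-genome sizes (positive).
#' @return An object of class `heaps_fit`: list with `kappa`, `gamma`, `b`,
#'   `r_squared`, `open` (`gamma > 0`), `converged`, `iterations`, the
#'   underlying `nls` fit and the data.
#' @examples
#' f <- fit_heaps(1:40, 10 * (1:40)^0.5 + 5)
#' glance(f)
#' @export
fit_heaps <- function(x, y) {
  if (length(x) < 4) pf_stop("need at least 4 points", "input")
  if (any(y <= 0)) pf_stop("y must be positive", "input")
  if (any(x < 1)) pf_stop("x must be >= 1", "input")
  dat <- data.frame(x = as.numeric(x), y = as.numeric(y))
  start <- list(kappa = max(y) - min(y), gamma = 0.5, b = min(y))
  if (start$kappa <= 0) start$kappa <- 1
  fit <- nls_restarts(y ~ kappa * x^gamma + b, dat, start,
                      lower = c(kappa = 0, gamma = -5, b = -Inf),
                      upper = c(kappa = Inf, gamma = 5, b = Inf))
  co <- coef(fit)
  structure(list(kappa = unname(co["kappa"]), gamma = unname(co["gamma"]),
                 b = unname(co["b"]),
                 r_squared = r_squared(dat$y, predict(fit)),
                 open = unname(co["gamma"]) > 0,
                 converged = fit$convInfo$isConv,
                 iterations = fit$convInfo$finIter,
                 fit = fit, data = as_tibble(dat)),
            class = "heaps_fit")
}

#' Fit an exponential decay model
#'
#' Nonlinear least squares of `y = A * exp(B * x) + K` with `B` constrained
#' negative, for series that decrease towards an asymptote: the core-genome
#' curve (K = projected core-genome size) or the new-genes-per-genome curve
#' (K = stable number of new gene families per added genome). An overall
#' increasing series is refused.
#'
#' @param x Genome counts (>= 4 points).
#' @param y Decreasing (or constant) series.
#' @return An object of class `decay_fit`: list with `A`, `B` (< 0), `K`
#'   (asymptote), `r_squared`, `converged`, `iterations`, fit and data.
#' @examples
#' f <- fit_decay(1:40, 500 * exp(-0.3 * (1:40)) + 3400)
#' f$K
#' @export
fit_decay <- function(x, y) {
  if (length(x) < 4) pf_stop("need at least 4 points", "input")
  if (y[length(y)] > y[1])
    pf_stop("series increases overall; exponential decay model refused",
            "input")
  dat <- data.frame(x = as.numeric(x), y = as.numeric(y))
  if (diff(range(y)) == 0) {
    # constant series: the decay amplitude is exactly zero
    return(structure(list(A = 0, B = -1, K = y[1], r_squared = 1,
                          converged = TRUE, iterations = 0L,
                          fit = NULL, data = as_tibble(dat)),
                     class = "decay_fit"))
  }
  start <- list(A = max(y[1] - y[length(y)], 1e-8), B = -0.1,
                K = y[length(y)])
  fit <- nls_restarts(y ~ A * exp(B * x) + K, dat, start,
                      lower = c(A = 0, B = -50, K = -Inf),
                      upper = c(A = Inf, B = -1e-12, K = Inf))
  co <- coef(fit)
  structure(list(A = unname(co["A"]), B = unname(co["B"]),
                 K = unname(co["K"]),
                 r_squared = r_squared(dat$y, predict(fit)),
                 converged = fit$convInfo$isConv,
                 iterations = fit$convInfo$finIter,
                 fit = fit, data = as_tibble(dat)),
            class = "decay_fit")
}

#' Open/closed pan-genome classification
#'
#' A pan-genome is called open when the fitted Heaps'-law exponent is
#' strictly positive, closed otherwise.
#'
#' @param fit A `heaps_fit` object (or a bare gamma value).
#' @return `"open"` or `"closed"`.
#' @export
classify_openness <- function(fit) {
  gamma <- if (inherits(fit, "heaps_fit")) fit$gamma else as.numeric(fit)
  if (gamma > 0) "open" else "closed"
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("<heaps_fit> y = %.4g * x^%.4g + %.4g  (R2 = %.4f, %s)\n",
              x$kappa, x$gamma, x$b, x$r_squared, classify_openness(x)))
  invisible(x)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> y = %.4g * exp(%.4g x) + %.4g  (R2 = %.4f)\n",
              x$A, x$B, x$K, x$r_squared))
  invisible(x)
}

#' @rdname fit_heaps
#' @param x A `heaps_fit`.
#' @param ... Unused.
#' @method tidy heaps_fit
#' @export
tidy.heaps_fit <- function(x, ...) {
  tibble(term = c("kappa", "gamma", "b"),
         estimate = c(x$kappa, x$gamma, x$b))
}

#' @rdname fit_heaps
#' @method glance heaps_fit
#' @export
glance.heaps_fit <- function(x, ...) {
  tibble(kappa = x$kappa, gamma = x$gamma, b = x$b,
         r.squared = x$r_squared, open = x$open, converged = x$converged,
         iterations = x$iterations, nobs = nrow(x$data))
}

#' @rdname fit_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("A", "B", "K"), estimate = c(x$A, x$B, x$K))
}

#' @rdname fit_decay
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  tibble(A = x$A, B = x$B, K = x$K, r.squared = x$r_squared,
         converged = x$converged, iterations = x$iterations,
         nobs = nrow(x$data))
}

fit_curve_plot <- function(object, label) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = 200))
  grid$y <- if (is.null(object$fit)) object$A * exp(object$B * grid$x) + object$K
            else predict(object$fit, newdata = grid)
  ggplot(object$data, aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "genomes", y = label)
}

#' @rdname fit_heaps
#' @param object A fitted model.
#' @method autoplot heaps_fit
#' @export
autoplot.heaps_fit <- function(object, ...) fit_curve_plot(object, "pan-genome size")

#' @rdname fit_decay
#' @param object A fitted model.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) fit_curve_plot(object, "gene families")
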