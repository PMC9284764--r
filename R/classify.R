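# PSO-optimized RBF-SVM classifier. PSO searches (log10 C, log10 gamma)
# maximizing stratified inner-cross-validation accuracy; the final SVM is
# refitted on all rows at the optimum.

#' Particle-swarm optimizer configuration
#'
#' Canonical constricted-PSO constants: inertia 0.72, cognitive and social
#' coefficients 1.49.
#'
#' @param swarm_size number of particles.
#' @param iterations number of velocity/position updates.
#' @param inertia,c1,c2 PSO coefficients (all must be positive).
#' @param seed integer seed for particle initialization and the stochastic
#'   updates.
#' @export
pso_config <- function(swarm_size = 30, iterations = 100, inertia = 0.72,
                       c1 = 1.49, c2 = 1.49, seed = NULL) {
  if (inertia <= 0 || c1 <= 0 || c2 <= 0)
    stop("PSO coefficients must be positive")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2, seed = seed),
            class = "pso_config")
}

#' Particle-swarm minimization over a box
#'
#' Velocity update `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with
#' positions clamped to the bounds. Returns the running global best, whose
#' per-iteration history is therefore monotone non-increasing.
#'
#' @param objective function of a numeric vector, returning a finite scalar.
#' @param lower,upper bound vectors (equal length; `lower <= upper`).
#' @param config a [pso_config()].
#' @return list with `par` (best position), `value` (best objective) and
#'   `history` (best value after each iteration, length `iterations`).
#' @export
pso_minimize <- function(objective, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper))
  if (any(lower > upper)) stop("lower bounds must not exceed upper bounds")
  d <- length(lower)
  span <- upper - lower
  with_seed(config$seed, {
    pos <- t(replicate(config$swarm_size, lower + runif(d) * span))
    if (d == 1) pos <- matrix(pos, ncol = 1)
    vel <- t(replicate(config$swarm_size,
                       (runif(d) - 0.5) * span))
    if (d == 1) vel <- matrix(vel, ncol = 1)
    eval_at <- function(x, i) {
      v <- objective(x)
      if (!is.finite(v))
        stop(sprintf("objective returned a non-finite value at particle %d",
                     i))
      v
    }
    fit <- vapply(seq_len(config$swarm_size),
                  function(i) eval_at(pos[i, ], i), 0)
    pbest <- pos
    pbest_fit <- fit
    g <- which.min(fit)
    gbest <- pos[g, ]
    gbest_fit <- fit[g]
    history <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(runif(config$swarm_size * d), ncol = d)
      r2 <- matrix(runif(config$swarm_size * d), ncol = d)
      vel <- config$inertia * vel +
        config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * (matrix(gbest, config$swarm_size, d,
                                 byrow = TRUE) - pos)
      pos <- pos + vel
      pos <- pmin(pmax(pos, matrix(lower, config$swarm_size, d,
                                   byrow = TRUE)),
                  matrix(upper, config$swarm_size, d, byrow = TRUE))
      fit <- vapply(seq_len(config$swarm_size),
                    function(i) eval_at(pos[i, ], i), 0)
      improved <- fit < pbest_fit
      pbest[improved, ] <- pos[improved, , drop = FALSE]
      pbest_fit[improved] <- fit[improved]
      g <- which.min(pbest_fit)
      if (pbest_fit[g] < gbest_fit) {
        gbest_fit <- pbest_fit[g]
        gbest <- pbest[g, ]
      }
      history[it] <- gbest_fit
    }
    list(par = gbest, value = gbest_fit, history = history)
  })
}

svm_cv_accuracy <- function(x, y, cost, gamma, folds) {
  correct <- 0L
  for (k in sort(unique(folds))) {
    tr <- folds != k
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

#' Train a PSO-optimized RBF SVM
#'
#' PSO searches `log10(C) in [-2, 3]` and `log10(gamma) in [-4, 1]`,
#' maximizing stratified inner-cross-validation accuracy; the returned model
#' is refitted on all rows at the optimum.
#'
#' @param features a `feature_matrix` (already standardized) or a plain
#'   numeric matrix.
#' @param labels two-class labels, one per row.
#' @param inner_folds stratified folds for the PSO fitness (default 3).
#' @param config a [pso_config()].
#' @param c_bounds,gamma_bounds log10 search bounds.
#' @return an `mi_classifier` with the fitted SVM, `C`, `gamma` and
#'   `pso_history` (best inner-CV accuracy per iteration, non-decreasing).
#' @export
train_pso_svm <- function(features, labels, inner_folds = 3,
                          config = pso_config(),
                          c_bounds = c(-2, 3), gamma_bounds = c(-4, 1)) {
  x <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) < 2) stop("training labels must contain two classes")
  if (min(table(y)) < inner_folds)
    stop("need at least inner_folds trials per class")
  folds <- stratified_folds(y, inner_folds, seed = config$seed %||% 0L)
  objective <- function(p)
    -svm_cv_accuracy(x, y, cost = 10^p[1], gamma = 10^p[2], folds)
  opt <- pso_minimize(objective,
                      lower = c(c_bounds[1], gamma_bounds[1]),
                      upper = c(c_bounds[2], gamma_bounds[2]),
                      config = config)
  C <- 10^opt$par[1]
  gamma <- 10^opt$par[2]
  fit <- e1071::svm(x, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, C = C, gamma = gamma,
                 cv_accuracy = -opt$value,
                 pso_history = -opt$history,
                 feature_names = colnames(x), classes = levels(y)),
            class = "mi_classifier")
}

#' @export
print.mi_classifier <- function(x, ...) {
  cat(sprintf("<mi_classifier: RBF SVM, C = %.4g, gamma = %.4g, inner-CV %.1f%%>\n",
              x$C, x$gamma, 100 * x$cv_accuracy))
  invisible(x)
}

#' Predict motor-imagery labels
#'
#' @param object an `mi_classifier`.
#' @param features a `feature_matrix` or numeric matrix whose columns match
#'   the training features.
#' @param ... unused.
#' @return list with `labels` (factor) and `margins` (signed decision
#'   values).
#' @export
predict.mi_classifier <- function(object, features, ...) {
  x <- if (inherits(features, "feature_matrix")) features$values
       else as.matrix(features)
  if (!is.null(object$feature_names) && !is.null(colnames(x)) &&
      !identical(colnames(x), object$feature_names))
    stop("feature columns do not match the training features")
  if (nrow(x) == 0)
    return(list(labels = factor(character(0), levels = object$classes),
                margins = numeric(0)))
  pred <- predict(object$fit, x, decision.values = TRUE)
  margins <- as.numeric(attr(pred, "decision.values"))
  list(labels = factor(as.character(pred), levels = object$classes),
       margins = margins)
}
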