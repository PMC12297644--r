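#' Hyperparameter search space
#'
#' Bounds for the four tuned hyperparameters. The learning rate is
#' searched on the log10 scale; epochs decode to the nearest integer.
#' The reference optimized setting (1e-4, 0.9, 30, 0.2) lies inside
#' the default space.
#'
#' @param lr_bounds learning-rate bounds (linear scale).
#' @param momentum_bounds,dropout_bounds linear bounds.
#' @param epochs_bounds integer bounds.
#' @return an object of class `search_space`.
#' @export
search_space <- function(lr_bounds = c(1e-5, 1e-1),
                         momentum_bounds = c(0.5, 0.99),
                         epochs_bounds = c(10L, 50L),
                         dropout_bounds = c(0, 0.5)) {
  chk <- function(b, nm) if (b[1] > b[2]) stopf("`%s` must be ordered", nm)
  chk(lr_bounds, "lr_bounds"); chk(momentum_bounds, "momentum_bounds")
  chk(epochs_bounds, "epochs_bounds"); chk(dropout_bounds, "dropout_bounds")
  structure(list(lr = lr_bounds, momentum = momentum_bounds,
                 epochs = as.integer(epochs_bounds),
                 dropout = dropout_bounds),
            class = "search_space")
}

#' Decode an AOA position into hyperparameters
#'
#' Position components live in `[0,1]^4` (clipped if outside):
#' learning rate by log10 interpolation, momentum and dropout
#' linearly, epochs rounded to the nearest integer in bounds.
#'
#' @param position numeric length-4 vector.
#' @param space a [search_space()].
#' @return list with `learning_rate`, `momentum`, `epochs`, `dropout`.
#' @export
decode_position <- function(position, space = search_space()) {
  if (length(position) != 4 || any(!is.finite(position)))
    stopf("`position` must be a finite length-4 vector")
  p <- pmin(pmax(position, 0), 1)
  llo <- log10(space$lr[1]); lhi <- log10(space$lr[2])
  list(learning_rate = 10^(llo + p[1] * (lhi - llo)),
       momentum = space$momentum[1] +
         p[2] * (space$momentum[2] - space$momentum[1]),
       epochs = as.integer(min(max(round(space$epochs[1] +
         p[3] * (space$epochs[2] - space$epochs[1])), space$epochs[1]),
         space$epochs[2])),
       dropout = space$dropout[1] +
         p[4] * (space$dropout[2] - space$dropout[1]))
}

#' Cross-validation fitness specification
#'
#' @param n_folds stratified folds (default 3).
#' @param seed integer seed controlling fold assignment and training.
#' @return an object of class `fitness_spec`.
#' @export
fitness_spec <- function(n_folds = 3L, seed = 1L) {
  if (n_folds < 2) stopf("`n_folds` must be >= 2")
  structure(list(n_folds = as.integer(n_folds), metric = "accuracy",
                 seed = as.integer(seed)),
            class = "fitness_spec")
}

#' Cross-validated accuracy of a hyperparameter setting
#'
#' Mean held-out accuracy over stratified folds -- the search fitness.
#' Features are standardized with training-fold statistics only.
#' Deterministic given the spec seed.
#'
#' @param hp hyperparameters from [decode_position()] (or a list with
#'   the same fields).
#' @param x,y features and 0/1 labels.
#' @param spec a [fitness_spec()].
#' @param net a [net_config()] template for the non-tuned settings.
#' @return mean validation accuracy in `[0, 1]`.
#' @export
cv_fitness <- function(hp, x, y, spec = fitness_spec(), net = net_config()) {
  x <- as.matrix(x); y <- as.integer(y)
  fold <- stratified_folds(y, spec$n_folds, seed = spec$seed)
  accs <- numeric(spec$n_folds)
  for (f in seq_len(spec$n_folds)) {
    tr <- fold != f
    if (length(unique(y[!tr])) < 2 || length(unique(y[tr])) < 2)
      stopf("fold %d contains a single class; use more data or fewer folds", f)
    cfg <- net
    cfg$learning_rate <- hp$learning_rate
    cfg$momentum <- hp$momentum
    cfg$epochs <- as.integer(hp$epochs)
    cfg$dropout_rate <- hp$dropout
    cfg$seed <- derive_seed(spec$seed, f)
    Xtr <- standardize_features(x[tr, , drop = FALSE])
    Xte <- standardize_features(x[!tr, , drop = FALSE],
                                attr(Xtr, "center"), attr(Xtr, "scale"))
    fit <- nn_train(cfg, Xtr, y[tr])
    probs <- nn_forward(fit$params, Xte, cfg, training = FALSE)
    accs[f] <- mean(as.integer(probs[, 2] > probs[, 1]) == y[!tr])
  }
  mean(accs)
}

#' Tune the classifier's hyperparameters with the AOA
#'
#' Couples the Archimedes optimizer to the classifier: AOA positions in
#' `[0,1]^4` decode to (learning rate, momentum, epochs, dropout), and
#' the fitness is stratified cross-validated accuracy (the optimizer
#' minimizes its negation). Repeated positions are memoized.
#'
#' @param x,y features and 0/1 labels.
#' @param space a [search_space()].
#' @param aoa an [aoa_config()] with `dim = 4` on `[0,1]^4`; default is
#'   the small desk budget (6 objects x 8 iterations).
#' @param spec a [fitness_spec()].
#' @param net a [net_config()] template.
#' @return an object of class `heart_net_search`: `best_hp`,
#'   `best_fitness` (CV accuracy), `aoa` (the `aoa_result`), and
#'   `log`, a data frame of every evaluated position.
#' @export
tune_heart_net <- function(x, y, space = search_space(), aoa = NULL,
                           spec = fitness_spec(), net = net_config()) {
  if (is.null(aoa))
    aoa <- aoa_config(dim = 4, lower = 0, upper = 1, pop_size = 6,
                      max_iter = 8, seed = spec$seed)
  stopifnot(aoa$dim == 4)
  memo <- new.env(parent = emptyenv())
  log_env <- new.env(parent = emptyenv())
  log_env$rows <- list()
  objective <- function(pos) {
    key <- paste(sprintf("%.15g", pos), collapse = ",")
    if (!is.null(memo[[key]])) return(memo[[key]])
    hp <- decode_position(pos, space)
    fit <- cv_fitness(hp, x, y, spec, net)
    memo[[key]] <- -fit
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(p1 = pos[1], p2 = pos[2], p3 = pos[3], p4 = pos[4],
                 learning_rate = hp$learning_rate, momentum = hp$momentum,
                 epochs = hp$epochs, dropout = hp$dropout, fitness = fit)
    -fit
  }
  res <- aoa_optimize(objective, aoa)
  best_hp <- decode_position(res$best_position, space)
  structure(list(best_hp = best_hp, best_fitness = -res$best_fitness,
                 aoa = res, log = do.call(rbind, log_env$rows),
                 space = space, spec = spec),
            class = "heart_net_search")
}

#' @export
print.heart_net_search <- function(x, ...) {
  cat("AOA hyperparameter search\n")
  cat(sprintf("  evaluations  : %d (after memoization)\n", nrow(x$log)))
  cat(sprintf("  best CV acc  : %.4f (%d-fold stratified)\n",
              x$best_fitness, x$spec$n_folds))
  cat(sprintf("  best setting : lr %.3g, momentum %.3f, %d epochs, dropout %.3f\n",
              x$best_hp$learning_rate, x$best_hp$momentum, x$best_hp$epochs,
              x$best_hp$dropout))
  invisible(x)
}

#' Persist a search trace
#'
#' The evaluation log as CSV and the best hyperparameters as JSON.
#'
#' @param search a `heart_net_search`.
#' @param csv_path,json_path output files (either may be NULL).
#' @export
write_search <- function(search, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    write.csv(search$log, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(search$best_hp, json_path, auto_unbox = TRUE,
                         digits = NA)
  invisible(search)
}
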