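#' Specification of a synthetic Cleveland-schema cohort
#'
#' The generator emulates the 13-feature Cleveland heart-disease schema
#' with a known generative model, so a Bayes-optimal reference
#' classifier exists. Labels are Bernoulli with the given prevalence;
#' continuous features are class-conditional Gaussians centred at the
#' published Cleveland means and shifted apart by
#' `effect_scale * sigma * w` along a fixed, documented direction `w`;
#' categorical features come from class-conditional tables whose
#' separation also scales with `effect_scale` (at 0 the classes are
#' indistinguishable). Missing values are injected into `ca` and `thal`
#' (the fields missing in the real file).
#'
#' @param n cohort size.
#' @param prevalence abnormal-class probability (default 0.46, the
#'   Cleveland rate).
#' @param effect_scale class-separation strength (default 2; 0 means no
#'   signal).
#' @param missing_rate per-cell missingness rate on `ca`/`thal`
#'   (default 0.01, matching the real file's sparsity).
#' @param seed integer seed; generation is fully reproducible.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 303L, prevalence = 0.46, effect_scale = 2,
                        missing_rate = 0.01, seed = NULL) {
  if (!is.numeric(n) || n < 0 || n != floor(n)) stopf("`n` must be >= 0")
  if (prevalence <= 0 || prevalence >= 1)
    stopf("`prevalence` must lie in (0, 1)")
  if (effect_scale < 0) stopf("`effect_scale` must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stopf("`missing_rate` must lie in [0, 1)")
  structure(list(n = as.integer(n), prevalence = prevalence,
                 effect_scale = effect_scale, missing_rate = missing_rate,
                 seed = seed),
            class = "cohort_spec")
}

# generative model constants: published Cleveland-range moments, a fixed
# shift direction for the continuous block, clip ranges, and
# class-conditional categorical tables at full separation.
cohort_model <- function() {
  cont <- data.frame(
    feature = c("age", "trestbps", "chol", "thalach", "oldpeak"),
    mean = c(54, 131, 246, 149, 1.0),
    sd = c(9, 17, 51, 23, 1.1),
    w = c(0.5, 0.35, 0.3, -0.6, 0.7),
    lo = c(29, 94, 126, 71, 0),
    hi = c(77, 200, 564, 202, 6.2))
  cat_tabs <- list(
    sex     = list(levels = c(0, 1), c0 = c(0.44, 0.56), c1 = c(0.18, 0.82)),
    cp      = list(levels = 1:4, c0 = c(0.12, 0.25, 0.40, 0.23),
                   c1 = c(0.03, 0.06, 0.12, 0.79)),
    fbs     = list(levels = c(0, 1), c0 = c(0.86, 0.14), c1 = c(0.84, 0.16)),
    restecg = list(levels = 0:2, c0 = c(0.56, 0.04, 0.40),
                   c1 = c(0.40, 0.04, 0.56)),
    exang   = list(levels = c(0, 1), c0 = c(0.86, 0.14), c1 = c(0.45, 0.55)),
    slope   = list(levels = 1:3, c0 = c(0.63, 0.30, 0.07),
                   c1 = c(0.26, 0.65, 0.09)),
    ca      = list(levels = 0:3, c0 = c(0.79, 0.13, 0.06, 0.02),
                   c1 = c(0.33, 0.32, 0.20, 0.15)),
    thal    = list(levels = c(3, 6, 7), c0 = c(0.79, 0.04, 0.17),
                   c1 = c(0.25, 0.08, 0.67)))
  list(cont = cont, cat = cat_tabs)
}

# class-conditional table at separation t in [0,1]
cat_table_at <- function(tab, y, t) {
  base <- (tab$c0 + tab$c1) / 2
  p <- base + t * ((if (y == 1) tab$c1 else tab$c0) - base)
  p / sum(p)
}

cleveland_feature_names <- function() {
  c("age", "sex", "cp", "trestbps", "chol", "fbs", "restecg", "thalach",
    "exang", "oldpeak", "slope", "ca", "thal")
}

#' Generate a synthetic patient cohort
#'
#' See [cohort_spec()] for the generative model. Continuous values are
#' clipped to physiological ranges; `oldpeak` is rounded to one
#' decimal, other continuous features to integers, matching the file
#' dialect.
#'
#' @param spec a [cohort_spec()].
#' @return data frame with `patient_id`, `name`, `location` metadata,
#'   the 13 clinical features, and a 0/1 `label` (1 = abnormal); the
#'   spec is attached as attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  mod <- cohort_model()
  n <- spec$n
  cols <- cleveland_feature_names()
  if (n == 0) {
    out <- data.frame(patient_id = character(), name = character(),
                      location = character())
    for (cl in cols) out[[cl]] <- numeric()
    out$label <- integer()
    attr(out, "spec") <- spec
    return(out)
  }
  local_seed(spec$seed, {
    y <- rbinom(n, 1, spec$prevalence)
    t <- min(spec$effect_scale / 2, 1)
    out <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      name = sprintf("Patient %04d", seq_len(n)),
      location = sample(c("Chennai", "Mumbai", "Delhi", "Hyderabad",
                          "Coimbatore"), n, replace = TRUE))
    for (cl in cols) out[[cl]] <- numeric(n)
    cc <- mod$cont
    for (i in seq_len(nrow(cc))) {
      f <- cc$feature[i]
      shift <- spec$effect_scale * cc$sd[i] * cc$w[i] / 2
      mu <- cc$mean[i] + ifelse(y == 1, shift, -shift)
      v <- pmin(pmax(rnorm(n, mu, cc$sd[i]), cc$lo[i]), cc$hi[i])
      out[[f]] <- if (f == "oldpeak") round(v, 1) else round(v)
    }
    for (f in names(mod$cat)) {
      tab <- mod$cat[[f]]
      p0 <- cat_table_at(tab, 0, t); p1 <- cat_table_at(tab, 1, t)
      v <- numeric(n)
      idx0 <- which(y == 0); idx1 <- which(y == 1)
      if (length(idx0))
        v[idx0] <- sample(tab$levels, length(idx0), TRUE, prob = p0)
      if (length(idx1))
        v[idx1] <- sample(tab$levels, length(idx1), TRUE, prob = p1)
      out[[f]] <- v
    }
    if (spec$missing_rate > 0) {
      for (f in c("ca", "thal")) {
        miss <- runif(n) < spec$missing_rate
        out[[f]][miss] <- NA
      }
    }
    out$label <- y
    attr(out, "spec") <- spec
    out
  })
}

#' Bayes-oracle classification from the generative model
#'
#' Computes the exact log-likelihood ratio of the generating model
#' (Gaussian terms for the continuous block, table terms for the
#' categoricals, plus the prior odds) and thresholds it at 0. Missing
#' entries contribute nothing. This upper-bounds the accuracy any
#' classifier can reach on cohorts from the same spec.
#'
#' @param cohort a cohort data frame from [generate_cohort()].
#' @param spec the [cohort_spec()] that generated it (defaults to the
#'   attached spec).
#' @return list with `label` (0/1 vector) and `score` (the LLR).
#' @export
bayes_oracle <- function(cohort, spec = attr(cohort, "spec")) {
  stopifnot(inherits(spec, "cohort_spec"))
  mod <- cohort_model()
  n <- nrow(cohort)
  t <- min(spec$effect_scale / 2, 1)
  llr <- rep(log(spec$prevalence / (1 - spec$prevalence)), n)
  cc <- mod$cont
  for (i in seq_len(nrow(cc))) {
    f <- cc$feature[i]
    shift <- spec$effect_scale * cc$sd[i] * cc$w[i] / 2
    x <- cohort[[f]]
    d1 <- stats::dnorm(x, cc$mean[i] + shift, cc$sd[i], log = TRUE)
    d0 <- stats::dnorm(x, cc$mean[i] - shift, cc$sd[i], log = TRUE)
    term <- d1 - d0
    term[is.na(term)] <- 0
    llr <- llr + term
  }
  for (f in names(mod$cat)) {
    tab <- mod$cat[[f]]
    p0 <- cat_table_at(tab, 0, t); p1 <- cat_table_at(tab, 1, t)
    ix <- match(cohort[[f]], tab$levels)
    term <- log(p1[ix]) - log(p0[ix])
    term[is.na(term)] <- 0
    llr <- llr + term
  }
  list(label = as.integer(llr > 0), score = llr)
}

#' Extract the model matrix and labels from a cohort
#'
#' Returns the 13 ordinal clinical features as a numeric matrix plus
#' the 0/1 label vector. Missing values are imputed by column median
#' (continuous) or mode (categorical) when `impute = TRUE`.
#'
#' @param cohort a cohort data frame.
#' @param impute impute missing entries (default TRUE).
#' @return list with `x` (matrix), `y` (integer vector) and
#'   `imputations` (named list of values used, possibly empty).
#' @export
cohort_features <- function(cohort, impute = TRUE) {
  cols <- cleveland_feature_names()
  x <- as.matrix(cohort[, cols])
  imputations <- list()
  if (impute && anyNA(x)) {
    cont <- c("age", "trestbps", "chol", "thalach", "oldpeak")
    for (cl in cols) {
      col <- x[, cl]
      if (!anyNA(col)) next
      val <- if (cl %in% cont) median(col, na.rm = TRUE) else {
        tb <- table(col)
        as.numeric(names(tb)[which.max(tb)])
      }
      x[is.na(col), cl] <- val
      imputations[[cl]] <- val
    }
  }
  list(x = x, y = as.integer(cohort$label), imputations = imputations)
}

#' Stratified train/test split
#'
#' Splits the cohort preserving the class ratio; reproducible under the
#' seed; the two parts are disjoint and their union is the cohort.
#'
#' @param cohort cohort data frame.
#' @param test_fraction fraction assigned to the test part.
#' @param seed integer seed.
#' @return list with `train` and `test` data frames.
#' @export
split_cohort <- function(cohort, test_fraction = 0.25, seed = NULL) {
  if (length(unique(cohort$label)) < 2)
    stopf("cannot stratify a single-class cohort")
  local_seed(seed, {
    test_idx <- unlist(lapply(split(seq_len(nrow(cohort)), cohort$label),
                              function(ix) {
      k <- round(length(ix) * test_fraction)
      sample(ix, k)
    }))
    test_idx <- sort(test_idx)
    sp <- attr(cohort, "spec")
    train <- cohort[-test_idx, , drop = FALSE]
    test <- cohort[test_idx, , drop = FALSE]
    attr(train, "spec") <- sp; attr(test, "spec") <- sp
    list(train = train, test = test)
  })
}

#' Stratified cross-validation fold assignment
#'
#' @param y 0/1 labels.
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold ids in `1:n_folds`.
#' @export
stratified_folds <- function(y, n_folds = 3L, seed = NULL) {
  if (n_folds < 2) stopf("`n_folds` must be >= 2")
  local_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      fold[ix] <- rep_len(seq_len(n_folds), length(ix))
    }
    fold
  })
}

#' Write a cohort in the processed-Cleveland CSV dialect
#'
#' 14 comma-separated fields per line (13 features + target), `"?"` for
#' missing values, no header unless requested. Metadata columns are not
#' written (the dialect has no room for them).
#'
#' @param cohort cohort data frame.
#' @param path output file.
#' @param header write a header line (non-standard; default FALSE).
#' @export
write_cleveland <- function(cohort, path, header = FALSE) {
  cols <- c(cleveland_feature_names(), "label")
  fmt <- lapply(cols, function(cl) {
    v <- as.numeric(cohort[[cl]])
    ifelse(is.na(v), "?", format(v, trim = TRUE, scientific = FALSE))
  })
  lines <- do.call(paste, c(fmt, sep = ","))
  if (header) lines <- c(paste(cols, collapse = ","), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read the processed-Cleveland CSV dialect
#'
#' Expects 14 comma-separated fields per line with `"?"` for missing.
#' The 0-4 target is binarized (0 = normal, 1-4 = abnormal). Missing
#' entries are imputed by column median (continuous) or mode
#' (categorical); the imputation values are recorded in the
#' `"imputations"` attribute.
#'
#' @param path input file.
#' @param header skip a leading header line.
#' @return cohort data frame (with generated `patient_id`s).
#' @export
read_cleveland <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  cols <- c(cleveland_feature_names(), "label")
  if (!length(lines)) {
    warning("empty Cleveland file: returning an empty cohort")
    out <- data.frame(patient_id = character())
    for (cl in cols) out[[cl]] <- numeric()
    return(out)
  }
  parts <- strsplit(lines, ",")
  m <- matrix(NA_real_, length(lines), 14)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    if (length(p) != 14)
      stopf("line %d has %d fields, expected 14", i + header, length(p))
    for (j in seq_len(14)) {
      if (p[j] == "?") next
      v <- suppressWarnings(as.numeric(p[j]))
      if (is.na(v)) stopf("unparseable value '%s' in field '%s' (line %d)",
                          p[j], cols[j], i + header)
      m[i, j] <- v
    }
  }
  out <- data.frame(patient_id = sprintf("P%04d", seq_along(lines)))
  for (j in seq_len(13)) out[[cols[j]]] <- m[, j]
  out$label <- as.integer(m[, 14] > 0)
  feat <- cohort_features(out, impute = TRUE)
  for (cl in names(feat$imputations)) out[[cl]] <- feat$x[, cl]
  attr(out, "imputations") <- feat$imputations
  out
}
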