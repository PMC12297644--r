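#' Local credential store with salted hashing
#'
#' The authentication stage reduced to a single-process stub: users
#' register with a username and a partial-key password, stored only as
#' `SHA-256(salt || password)` with a unique random salt. Login
#' rejections for unknown users and wrong passwords are
#' indistinguishable. A failed verification routes the caller back to
#' registration.
#'
#' @return `credential_store()`: an empty store (environment).
#' @export
credential_store <- function() new.env(parent = emptyenv())

#' @rdname credential_store
#' @param store a credential store.
#' @param username,password credentials; usernames must be unique at
#'   registration.
#' @param role one of "patient", "hospital", "admin".
#' @export
register_user <- function(store, username, password,
                          role = c("patient", "hospital", "admin")) {
  role <- match.arg(role)
  if (!is.null(store[[username]])) stopf("user '%s' already registered", username)
  salt <- openssl::rand_bytes(16)
  store[[username]] <- list(salt = salt,
                            hash = sha256_raw(c(salt, charToRaw(password))),
                            role = role)
  invisible(TRUE)
}

#' @rdname credential_store
#' @param ttl session lifetime in seconds.
#' @return `login_user`: a session list on success, `NULL` on
#'   rejection (with a message that does not reveal which credential
#'   failed).
#' @export
login_user <- function(store, username, password, ttl = 3600) {
  cred <- store[[username]]
  ok <- !is.null(cred) &&
    identical(sha256_raw(c(cred$salt, charToRaw(password))), cred$hash)
  if (!ok) {
    message("login rejected: invalid username or password")
    return(NULL)
  }
  list(username = username, role = cred$role,
       token = hex(openssl::rand_bytes(16)),
       expires = as.numeric(Sys.time()) + ttl)
}

#' @rdname credential_store
#' @param session a session from [login_user()].
#' @return `verify_session`: `TRUE` iff the session exists and is
#'   unexpired; on `FALSE` the caller should return to registration.
#' @export
verify_session <- function(session) {
  !is.null(session) && is.list(session) &&
    as.numeric(Sys.time()) < session$expires
}

# canonical byte serialization of one patient record (id + the 14-field
# CSV line); this is what gets encrypted and committed
record_bytes <- function(cohort) {
  cols <- c(cleveland_feature_names(), "label")
  out <- list()
  for (i in seq_len(nrow(cohort))) {
    v <- vapply(cols, function(cl) {
      x <- cohort[[cl]][i]
      if (is.na(x)) "?" else format(as.numeric(x), trim = TRUE,
                                    scientific = FALSE)
    }, character(1))
    out[[cohort$patient_id[i]]] <-
      charToRaw(paste(c(cohort$patient_id[i], v), collapse = ","))
  }
  out
}

cipher_to_bytes <- function(blocks) {
  do.call(c, lapply(blocks, function(b) do.call(c, lapply(b, u_be, width = 8))))
}

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] (generate) or a file path (read the
#'   processed-Cleveland dialect).
#' @param test_fraction held-out fraction for evaluation.
#' @param key_bits,k,chain cipher settings (see [rsa_keygen()]).
#' @param tune run the AOA hyperparameter search (default FALSE: use
#'   the baseline [net_config()] verbatim).
#' @param net baseline [net_config()].
#' @param aoa_pop,aoa_iter AOA search budget when tuning.
#' @param n_folds CV folds for the search fitness.
#' @param seed root seed; every stage derives its own stream from it.
#' @param timestamp logical clock for ledger blocks (an integer;
#'   defaults to 0 so that runs are bitwise reproducible).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), test_fraction = 0.25,
                            key_bits = 32L, k = 2L, chain = FALSE,
                            tune = FALSE, net = net_config(),
                            aoa_pop = 6L, aoa_iter = 8L, n_folds = 3L,
                            seed = 1L, timestamp = 0L) {
  structure(list(cohort = cohort, test_fraction = test_fraction,
                 key_bits = as.integer(key_bits), k = as.integer(k),
                 chain = chain, tune = tune, net = net,
                 aoa_pop = as.integer(aoa_pop),
                 aoa_iter = as.integer(aoa_iter),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 timestamp = as.integer(timestamp)),
            class = "pipeline_config")
}

#' Run the secured prediction pipeline end to end
#'
#' Stages, in order: (1) generate or load the cohort; (2) key
#' generation (timed); (3) per-record encryption (timed); (4) ledger
#' commit with Merkle root; (5) audit + hash-chained log check; (6)
#' decryption of every record (timed) with a byte-equality assertion
#' against the originals; (7) classifier training (baseline or
#' AOA-tuned) on the decrypted training split; (8) prediction on the
#' test split; (9) evaluation metrics; (10) alert objects for
#' predicted-abnormal patients. Any integrity failure aborts with the
#' stage name. Identical configs and seeds give identical reports
#' except for the `hardware_dependent` section.
#'
#' @param config a [pipeline_config()].
#' @param tamper_id for integrity testing only: a record id whose
#'   stored ciphertext is corrupted after the ledger commit (the audit
#'   stage must then abort).
#' @return a `pipeline_report` list; see Details.
#' @export
run_pipeline <- function(config, tamper_id = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- list()
  timings <- list()
  mark <- function(name) stages[[name]] <<- "ok"

  # (1) cohort
  cohort <- if (is.character(config$cohort)) read_cleveland(config$cohort)
    else {
      sp <- config$cohort
      sp$seed <- sp$seed %||% derive_seed(config$seed, 1L)
      generate_cohort(sp)
    }
  if (nrow(cohort) == 0) stopf("pipeline aborted at stage 'cohort': empty cohort")
  mark("cohort")

  # (2) keygen
  kg <- time_phase("key_generation", function()
    rsa_keygen(config$key_bits, config$k, seed = derive_seed(config$seed, 2L)))
  keys <- kg$result; timings$key_generation <- kg$timing
  mark("keygen")

  # (3) encrypt
  plain <- record_bytes(cohort)
  enc <- time_phase("encryption", function()
    lapply(plain, encrypt_record, public = keys$public, chain = config$chain))
  ciphers <- enc$result; timings$encryption <- enc$timing
  storage <- lapply(ciphers, cipher_to_bytes)
  mark("encrypt")

  # (4) ledger commit
  chain <- local_seed(derive_seed(config$seed, 4L), {
    ch <- new_chain()
    append_block(ch, storage, timestamp = config$timestamp)
  })
  cv <- verify_chain(chain)
  if (!cv$valid) stopf("pipeline aborted at stage 'ledger': chain invalid")
  mark("ledger")

  # optional corruption between commit and audit (integrity testing)
  if (!is.null(tamper_id)) {
    if (is.null(storage[[tamper_id]])) stopf("unknown tamper_id '%s'", tamper_id)
    b <- storage[[tamper_id]]
    b[1] <- as.raw(bitwXor(as.integer(b[1]), 1L))
    storage[[tamper_id]] <- b
  }

  # (5) audit + log
  audit <- audit_chain(chain, storage)
  log <- generate_log(NULL, audit, block_index = 1L,
                      timestamp = config$timestamp)
  if (!check_log(log)) stopf("pipeline aborted at stage 'audit': log chain invalid")
  if (!audit$pass)
    stopf("pipeline aborted at stage 'audit': integrity failure for record(s) %s",
          paste(unique(audit$failures$id), collapse = ", "))
  mark("audit")

  # (6) decrypt + byte equality
  dec <- time_phase("decryption", function()
    lapply(ciphers, decrypt_record, private = keys$private,
           chain = config$chain))
  decrypted <- dec$result; timings$decryption <- dec$timing
  equal <- mapply(identical, decrypted, plain[names(decrypted)])
  if (!all(equal))
    stopf("pipeline aborted at stage 'decrypt': decrypted bytes differ for %s",
          paste(names(decrypted)[!equal], collapse = ", "))
  mark("decrypt")

  # (7) train on the decrypted training split
  decoded <- do.call(rbind, lapply(decrypted, function(b) {
    parts <- strsplit(rawToChar(b), ",")[[1]]
    vals <- suppressWarnings(as.numeric(ifelse(parts[-1] == "?", NA,
                                               parts[-1])))
    c(vals)
  }))
  dec_cohort <- data.frame(patient_id = names(decrypted))
  cols <- c(cleveland_feature_names(), "label")
  for (j in seq_along(cols)) dec_cohort[[cols[j]]] <- decoded[, j]
  dec_cohort$label <- as.integer(dec_cohort$label)
  if (length(unique(dec_cohort$label)) < 2)
    stopf("pipeline aborted at stage 'train': single-class data")
  sp <- split_cohort(dec_cohort, config$test_fraction,
                     seed = derive_seed(config$seed, 7L))
  ftr <- cohort_features(sp$train); fte <- cohort_features(sp$test)
  net <- config$net
  search <- NULL
  if (config$tune) {
    search <- tune_heart_net(
      ftr$x, ftr$y,
      aoa = aoa_config(dim = 4, lower = 0, upper = 1,
                       pop_size = config$aoa_pop, max_iter = config$aoa_iter,
                       seed = derive_seed(config$seed, 8L)),
      spec = fitness_spec(config$n_folds, derive_seed(config$seed, 9L)),
      net = net)
    net$learning_rate <- search$best_hp$learning_rate
    net$momentum <- search$best_hp$momentum
    net$epochs <- search$best_hp$epochs
    net$dropout_rate <- search$best_hp$dropout
  }
  net$seed <- derive_seed(config$seed, 10L)
  model <- heart_net(ftr$x, ftr$y, net, x_val = fte$x, y_val = fte$y)
  mark("train")

  # (8) predict
  probs <- predict(model, fte$x, type = "prob")
  pred <- as.integer(probs[, 2] > probs[, 1])
  mark("predict")

  # (9) metrics
  cc <- confusion_from_labels(fte$y, pred)
  metrics <- classification_metrics(cc)
  mark("metrics")

  # (10) alerts for predicted-abnormal
  alerts <- lapply(which(pred == 1), function(i) {
    list(patient_id = sp$test$patient_id[i], predicted_class = 1L,
         probability = unname(probs[i, 2]), timestamp = config$timestamp,
         delivery = "stub://mobile")
  })
  mark("alert")

  report <- list(
    stages = stages,
    seed = config$seed,
    cohort = list(n = nrow(cohort),
                  prevalence = mean(cohort$label),
                  source = if (is.character(config$cohort)) "file"
                           else "synthetic"),
    keys = list(bits = bits_of(keys$public$n), k = keys$public$k),
    ledger = list(blocks = length(chain),
                  merkle_root = hex(chain[[1]]$merkle_root),
                  audit_pass = audit$pass, log_valid = check_log(log)),
    integrity = list(decrypted_equal = all(equal),
                     n_records = length(decrypted)),
    model = list(tuned = config$tune,
                 hyperparameters = list(learning_rate = net$learning_rate,
                                        momentum = net$momentum,
                                        epochs = net$epochs,
                                        dropout = net$dropout_rate),
                 cv_fitness = if (config$tune) search$best_fitness else NULL,
                 final_train_accuracy =
                   model$report$train_acc[nrow(model$report)]),
    confusion = list(tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn),
    metrics = metrics,
    alerts = alerts,
    hardware_dependent = list(timings = timings,
                              wall_clock = as.numeric(Sys.time()))
  )
  class(report) <- "pipeline_report"
  attr(report, "model") <- model
  attr(report, "keys") <- keys
  attr(report, "chain") <- chain
  attr(report, "search") <- search
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat("  stages   :", paste(names(x$stages), collapse = " -> "), "\n")
  cat(sprintf("  cohort   : n = %d (%s), prevalence %.2f\n", x$cohort$n,
              x$cohort$source, x$cohort$prevalence))
  cat(sprintf("  ledger   : %d block(s), audit %s, log %s\n",
              x$ledger$blocks, if (x$ledger$audit_pass) "pass" else "FAIL",
              if (x$ledger$log_valid) "valid" else "INVALID"))
  cat(sprintf("  integrity: decrypted bytes equal originals: %s (%d records)\n",
              x$integrity$decrypted_equal, x$integrity$n_records))
  cat(sprintf("  accuracy : %.4f | precision %.4f | recall %.4f | F1 %.4f\n",
              x$metrics$accuracy, x$metrics$precision, x$metrics$recall,
              x$metrics$f1))
  cat(sprintf("  alerts   : %d predicted-abnormal patient(s)\n",
              length(x$alerts)))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' The `hardware_dependent` section holds all wall-clock quantities;
#' the rest of the report is reproducible under a fixed seed.
#'
#' @param report a `pipeline_report`.
#' @param path output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
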