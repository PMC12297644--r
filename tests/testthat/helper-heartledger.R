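# shared fixtures, built in code

# the hand-verifiable worked key: n = 5*7 = 35, e = d = 5 (phi = 24),
# mixing matrix [[1,1],[0,1]] with inverse [[1,34],[0,1]] mod 35
hand_keys <- function() {
  list(public = structure(list(n = 35, e = 5,
                               A = matrix(c(1, 0, 1, 1), 2, 2), k = 2L),
                          class = "rsa_public_key"),
       private = structure(list(n = 35, d = 5,
                                A_inv = matrix(c(1, 0, 34, 1), 2, 2),
                                k = 2L, primes = c(5, 7)),
                           class = "rsa_private_key"))
}

# independent SHA-256 oracle for the Merkle construction
H <- function(...) as.raw(openssl::sha256(c(...)))
b0 <- as.raw(0x00); b1 <- as.raw(0x01)

flip_bit <- function(bytes, bit) {
  i <- (bit - 1) %/% 8 + 1
  mask <- bitwShiftL(1L, (bit - 1) %% 8)
  bytes[i] <- as.raw(bitwXor(as.integer(bytes[i]), mask))
  bytes
}

random_raw <- function(n) as.raw(sample.int(256, n, replace = TRUE) - 1L)

small_cohort <- function(n = 120, effect = 2, seed = 1, ...)
  generate_cohort(cohort_spec(n = n, effect_scale = effect, seed = seed, ...))

# flatten/unflatten trainable parameters (finite-difference probes)
nn_flatten <- function(params) {
  nm <- setdiff(names(params), c("run_mean", "run_var"))
  unlist(lapply(params[nm], as.vector))
}
nn_unflatten <- function(params, v) {
  i <- 1
  for (nm in setdiff(names(params), c("run_mean", "run_var"))) {
    len <- length(params[[nm]])
    params[[nm]][] <- v[i:(i + len - 1)]
    i <- i + len
  }
  params
}

# central finite-difference gradient of the training loss
nn_fd_grad <- function(params, X, y, cfg, h = 1e-5) {
  v <- nn_flatten(params)
  g <- numeric(length(v))
  for (i in seq_along(v)) {
    vp <- v; vp[i] <- v[i] + h
    vm <- v; vm[i] <- v[i] - h
    lp <- heartledger:::nn_loss_grad(nn_unflatten(params, vp), X, y, cfg)$loss
    lm <- heartledger:::nn_loss_grad(nn_unflatten(params, vm), X, y, cfg)$loss
    g[i] <- (lp - lm) / (2 * h)
  }
  g
}

nn_analytic_grad <- function(params, X, y, cfg) {
  lg <- heartledger:::nn_loss_grad(params, X, y, cfg)
  out <- numeric(0)
  for (nm in setdiff(names(params), c("run_mean", "run_var"))) {
    g <- lg$grad[[nm]]
    out <- c(out, if (is.null(g)) rep(0, length(params[[nm]]))
             else as.vector(g))
  }
  out
}
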