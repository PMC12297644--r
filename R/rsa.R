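#' Matrix-based RSA block cipher
#'
#' A Hill-style hybrid: an invertible k x k mixing matrix over `Z_n`
#' is applied to each k-block of plaintext integers, then every
#' component is RSA-exponentiated (`c = (A m)^e mod n`). Decryption
#' applies the inverse exponent and then the inverse matrix. Because
#' `n` is squarefree, the RSA map is a bijection on all of `Z_n`, so
#' correctness holds even for block entries sharing a factor with `n`.
#'
#' This construction is educational: it preserves the ingredients of
#' the scheme (two primes, the totient, an invertible matrix, its
#' modular inverse for decryption, block count set by the matrix) but
#' is NOT audited cryptography and must not protect real data.
#'
#' @name matrix_rsa
NULL

bits_of <- function(n) {
  b <- 0L
  while (n >= 1) { n <- n / 2; b <- b + 1L }
  b
}

rand_int_below <- function(m) {
  # uniform integer in [0, m) from the R stream, exact for m <= 2^52
  hi <- floor(runif(1) * 67108864)         # 26 bits
  lo <- floor(runif(1) * 67108864)
  (hi * 67108864 + lo) %% m
}

rand_prime <- function(bits) {
  lo <- 2^(bits - 1)
  repeat {
    cand <- lo + rand_int_below(lo)
    cand <- cand + (1 - cand %% 2)         # force odd
    if (cand >= 2 * lo) next
    if (.is_prime(cand)) return(cand)
  }
}

# determinant of an integer matrix mod n, by recursive expansion
det_mod <- function(A, n) {
  k <- nrow(A)
  if (k == 1) return(A[1, 1] %% n)
  if (k == 2) {
    ad <- .mod_mul(A[1, 1], A[2, 2], n)
    bc <- .mod_mul(A[1, 2], A[2, 1], n)
    return((ad - bc) %% n)
  }
  acc <- 0
  for (j in seq_len(k)) {
    minor <- A[-1, -j, drop = FALSE]
    term <- .mod_mul(A[1, j], det_mod(minor, n), n)
    acc <- (acc + if (j %% 2 == 1) term else (n - term) %% n) %% n
  }
  acc
}

#' Invert a matrix modulo n
#'
#' Adjugate-based inverse over `Z_n`: requires `gcd(det(A) mod n, n)
#' = 1`. If the determinant shares a nontrivial factor with `n` the
#' error message does not disclose it (it would factor the modulus).
#'
#' @param A square integer matrix (entries reduced mod `n`).
#' @param n modulus.
#' @return matrix `A_inv` with `A %*% A_inv == I (mod n)`.
#' @export
matrix_inverse_mod <- function(A, n) {
  A <- as.matrix(A) %% n
  k <- nrow(A)
  if (ncol(A) != k) stopf("matrix must be square")
  dt <- det_mod(A, n)
  dinv <- .mod_inv(dt, n)
  if (dinv < 0) stopf("matrix is not invertible modulo n")
  if (k == 1) return(matrix(dinv, 1, 1))
  adj <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    minor <- A[-i, -j, drop = FALSE]
    cof <- det_mod(minor, n)
    if ((i + j) %% 2 == 1) cof <- (n - cof) %% n
    adj[j, i] <- cof
  }
  matrix(.mod_mul(as.vector(adj), dinv, n), k, k)
}

mat_vec_mod <- function(A, v, n) {
  k <- nrow(A)
  out <- numeric(k)
  for (i in seq_len(k)) {
    s <- 0
    prods <- .mod_mul(A[i, ], v, n)
    for (p in prods) s <- (s + p) %% n
    out[i] <- s
  }
  out
}

#' Generate a matrix-RSA key pair
#'
#' Draws two distinct seeded Miller-Rabin primes of about
#' `bit_length/2` bits, sets `e = 65537` (or the next exponent coprime
#' to the totient), `d = e^-1 mod phi(n)`, and samples a uniform k x k
#' matrix over `Z_n` until it is invertible (at most 1000 draws). The
#' same seed always yields the same keys.
#'
#' @param bit_length approximate modulus size in bits (16-52; default
#'   32 -- test scale, see [matrix_rsa]).
#' @param k block size (matrix dimension, >= 1).
#' @param seed integer seed.
#' @return list with `public` (n, e, A, k) and `private` (n, d, A_inv,
#'   k, and the primes, retained for testing only).
#' @export
rsa_keygen <- function(bit_length = 32L, k = 2L, seed = NULL) {
  if (bit_length < 16 || bit_length > 52)
    stopf("`bit_length` must lie in [16, 52]")
  if (!is_count(k)) stopf("`k` must be a positive integer")
  local_seed(seed, {
    pb <- ceiling(bit_length / 2)
    x <- rand_prime(pb)
    repeat { y <- rand_prime(pb); if (y != x) break }
    n <- x * y
    phi <- (x - 1) * (y - 1)
    e <- 65537
    if (e >= phi) e <- 3
    while (.gcd_u64(e, phi) != 1) e <- e + 2
    d <- .mod_inv(e, phi)
    A <- NULL
    for (try in seq_len(1000)) {
      cand <- matrix(vapply(seq_len(k * k), function(i) rand_int_below(n),
                            numeric(1)), k, k)
      if (.gcd_u64(det_mod(cand, n), n) == 1) { A <- cand; break }
    }
    if (is.null(A)) stopf("failed to draw an invertible matrix in 1000 tries")
    A_inv <- matrix_inverse_mod(A, n)
    list(public = structure(list(n = n, e = e, A = A, k = as.integer(k)),
                            class = "rsa_public_key"),
         private = structure(list(n = n, d = d, A_inv = A_inv,
                                  k = as.integer(k), primes = c(x, y)),
                             class = "rsa_private_key"))
  })
}

#' @export
print.rsa_public_key <- function(x, ...) {
  cat(sprintf("matrix-RSA public key: %d-bit modulus, e = %.0f, block size k = %d\n",
              bits_of(x$n), x$e, x$k))
  invisible(x)
}

#' @export
print.rsa_private_key <- function(x, ...) {
  cat(sprintf("matrix-RSA private key: %d-bit modulus, block size k = %d\n",
              bits_of(x$n), x$k))
  invisible(x)
}

#' Encode bytes into plaintext blocks
#'
#' The byte string is length-prefixed, split big-endian into chunks of
#' `floor((bits(n) - 1)/8)` bytes (each chunk an integer `< n`), and
#' zero-padded to a multiple of the block size `k`. Deterministic.
#'
#' @param record raw vector or single character string.
#' @param key a key with fields `n` and `k` (public or private).
#' @return list of numeric k-vectors (plain blocks).
#' @export
encode_record <- function(record, key) {
  if (is.character(record)) record <- charToRaw(record)
  if (!length(record)) stopf("cannot encode an empty record")
  n <- key$n; k <- key$k
  if (n <= 2^17) stopf("modulus too small for byte encoding (need n > 2^17)")
  cw <- (bits_of(n) - 1) %/% 8
  len <- length(record)
  if (len >= n) stopf("record too long for this modulus")
  pad <- (cw - len %% cw) %% cw
  bytes <- c(record, as.raw(rep(0, pad)))
  nchunk <- length(bytes) / cw
  chunks <- numeric(nchunk)
  for (i in seq_len(nchunk)) {
    v <- 0
    for (b in bytes[((i - 1) * cw + 1):(i * cw)]) v <- v * 256 + as.integer(b)
    chunks[i] <- v
  }
  ints <- c(len, chunks)
  padk <- (k - length(ints) %% k) %% k
  ints <- c(ints, rep(0, padk))
  split(ints, ceiling(seq_along(ints) / k))
}

#' Decode plaintext blocks back to bytes
#'
#' Inverse of [encode_record()].
#'
#' @param blocks list of numeric k-vectors.
#' @param key key with fields `n` and `k`.
#' @return raw vector.
#' @export
decode_record <- function(blocks, key) {
  ints <- unlist(blocks, use.names = FALSE)
  if (!length(ints)) return(raw(0))
  cw <- (bits_of(key$n) - 1) %/% 8
  len <- ints[1]
  chunks <- ints[-1]
  bytes <- raw(0)
  for (v in chunks) {
    b <- raw(cw)
    for (i in cw:1) { b[i] <- as.raw(v %% 256); v <- v %/% 256 }
    bytes <- c(bytes, b)
  }
  bytes[seq_len(len)]
}

#' Encrypt plaintext blocks
#'
#' Per block `M`: mix `C = A M mod n`, then exponentiate each
#' component `c_i = C_i^e mod n`. With `chain = TRUE` the previous
#' cipher block is added (mod n) to the next plain block before mixing
#' (CBC-style confusion; default off).
#'
#' @param blocks list of numeric k-vectors with entries in `[0, n)`.
#' @param public an `rsa_public_key`.
#' @param chain chain blocks (default FALSE).
#' @return list of cipher blocks (numeric k-vectors).
#' @export
rsa_encrypt <- function(blocks, public, chain = FALSE) {
  n <- public$n; k <- public$k
  prev <- numeric(k)
  lapply(blocks, function(m) {
    if (length(m) != k) stopf("block length %d != k = %d", length(m), k)
    if (any(m >= n | m < 0)) stopf("block entry outside [0, n)")
    if (chain) m <- (m + prev) %% n
    mixed <- mat_vec_mod(public$A, m, n)
    ct <- .mod_pow(mixed, public$e, n)
    if (chain) prev <<- ct
    ct
  })
}

#' Decrypt cipher blocks
#'
#' Per block: `m' = c^d mod n` componentwise, then `M = A_inv m' mod
#' n` (minus the previous cipher block when chaining).
#'
#' @param cipher list of cipher blocks.
#' @param private an `rsa_private_key`.
#' @param chain must match the encryption setting.
#' @return list of plain blocks.
#' @export
rsa_decrypt <- function(cipher, private, chain = FALSE) {
  n <- private$n; k <- private$k
  prev <- numeric(k)
  lapply(cipher, function(ct) {
    if (length(ct) != k) stopf("cipher block length %d != k = %d",
                               length(ct), k)
    if (any(ct >= n | ct < 0)) stopf("cipher entry outside [0, n)")
    mixed <- .mod_pow(ct, private$d, n)
    m <- mat_vec_mod(private$A_inv, mixed, n)
    if (chain) { m <- (m - prev) %% n; prev <<- ct }
    m
  })
}

#' Encrypt / decrypt a byte record end to end
#'
#' Convenience composition of [encode_record()], [rsa_encrypt()] /
#' [rsa_decrypt()], [decode_record()].
#'
#' @param record raw vector or string.
#' @param public,private keys from [rsa_keygen()].
#' @param chain chaining flag.
#' @return `encrypt_record`: list of cipher blocks; `decrypt_record`:
#'   raw vector.
#' @export
encrypt_record <- function(record, public, chain = FALSE) {
  rsa_encrypt(encode_record(record, public), public, chain = chain)
}

#' @rdname encrypt_record
#' @param cipher list of cipher blocks.
#' @export
decrypt_record <- function(cipher, private, chain = FALSE) {
  decode_record(rsa_decrypt(cipher, private, chain = chain), private)
}

int_str <- function(x) sprintf("%.0f", x)

#' Serialize keys to JSON
#'
#' Big integers are written as decimal strings; the matrix in
#' row-major order. `read_keys()` restores both halves.
#'
#' @param keys list with `public` and `private` from [rsa_keygen()].
#' @param path output file.
#' @export
write_keys <- function(keys, path) {
  pub <- keys$public; priv <- keys$private
  obj <- list(
    format = "heartledger-keys-v1",
    public = list(n = int_str(pub$n), e = int_str(pub$e), k = pub$k,
                  A = matrix(int_str(pub$A), pub$k, pub$k)),
    private = list(n = int_str(priv$n), d = int_str(priv$d), k = priv$k,
                   A_inv = matrix(int_str(priv$A_inv), priv$k, priv$k)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_keys
#' @export
read_keys <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "heartledger-keys-v1"))
    stopf("unrecognized key file format")
  k <- as.integer(obj$public$k)
  list(public = structure(list(n = as.numeric(obj$public$n),
                               e = as.numeric(obj$public$e),
                               A = matrix(as.numeric(obj$public$A), k, k),
                               k = k), class = "rsa_public_key"),
       private = structure(list(n = as.numeric(obj$private$n),
                                d = as.numeric(obj$private$d),
                                A_inv = matrix(as.numeric(obj$private$A_inv),
                                               k, k),
                                k = k), class = "rsa_private_key"))
}

#' Serialize ciphertext to JSON
#'
#' Blocks are written as arrays of decimal strings under a header
#' recording `k`, the modulus width and the chaining flag.
#'
#' @param cipher list of cipher blocks.
#' @param public the public key (for the header).
#' @param path output file.
#' @param chain chaining flag recorded in the header.
#' @export
write_cipher <- function(cipher, public, path, chain = FALSE) {
  obj <- list(format = "heartledger-cipher-v1", k = public$k,
              bits = bits_of(public$n), chain = chain,
              blocks = lapply(cipher, int_str))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cipher
#' @export
read_cipher <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "heartledger-cipher-v1"))
    stopf("unrecognized cipher file format")
  lapply(obj$blocks, function(b) as.numeric(unlist(b)))
}
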