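test_that("the hand-worked key encrypts (2,3) to (10,33) and decrypts it back", {
  k <- hand_keys()
  # 5*5 = 25 = 1 mod 24, so d = e = 5
  expect_equal((5 * 5) %% 24, 1)
  ct <- rsa_encrypt(list(c(2, 3)), k$public)
  expect_equal(ct[[1]], c(10, 33))
  expect_equal(rsa_decrypt(ct, k$private)[[1]], c(2, 3))
  # scalar k = 1 case: c = 2^5 mod 35 = 32
  pub1 <- structure(list(n = 35, e = 5, A = matrix(1, 1, 1), k = 1L),
                    class = "rsa_public_key")
  expect_equal(rsa_encrypt(list(2), pub1)[[1]], 32)
  # degenerate parameters: identity matrix, e = 1 -> ciphertext = plaintext
  pub_id <- structure(list(n = 35, e = 1, A = diag(2), k = 2L),
                      class = "rsa_public_key")
  expect_equal(rsa_encrypt(list(c(4, 9)), pub_id)[[1]], c(4, 9))
})

test_that("RSA map stays bijective when a block entry shares a factor with n", {
  k <- hand_keys()
  ct <- rsa_encrypt(list(c(5, 7)), k$public)   # gcd(5,35), gcd(7,35) > 1
  expect_equal(rsa_decrypt(ct, k$private)[[1]], c(5, 7))
})

test_that("modular matrix inversion matches hand results and rejects singular input", {
  expect_equal(matrix_inverse_mod(diag(3), 35), diag(3))
  A <- matrix(c(1, 0, 1, 1), 2, 2)
  Ainv <- matrix_inverse_mod(A, 35)
  expect_equal(Ainv, matrix(c(1, 0, 34, 1), 2, 2))
  prod <- matrix(heartledger:::.mod_mul(
    c(A %*% Ainv), 1, 35), 2, 2)
  expect_equal(prod %% 35, diag(2))
  expect_error(matrix_inverse_mod(matrix(c(2, 1, 4, 2), 2, 2), 35),
               "not invertible")
  # the error must not disclose a factor of n
  err <- tryCatch(matrix_inverse_mod(matrix(5, 1, 1), 35),
                  error = conditionMessage)
  expect_false(grepl("\\b5\\b|\\b7\\b", err))
})

test_that("seeded key generation is deterministic and yields valid inverses", {
  k1 <- rsa_keygen(24, 2, seed = 5)
  k2 <- rsa_keygen(24, 2, seed = 5)
  expect_identical(k1, k2)
  for (s in 1:10) for (kk in 1:3) {
    keys <- rsa_keygen(24, kk, seed = s)
    n <- keys$public$n
    x <- keys$private$primes[1]; y <- keys$private$primes[2]
    expect_true(heartledger:::.is_prime(x) && heartledger:::.is_prime(y))
    expect_true(x != y)
    expect_equal(x * y, n)
    phi <- (x - 1) * (y - 1)
    expect_equal(heartledger:::.mod_mul(keys$public$e %% phi,
                                        keys$private$d, phi), 1)
    # A * A_inv = I (mod n)
    AA <- keys$public$A %*% keys$private$A_inv
    expect_equal(round(AA) %% n, diag(kk))
  }
})

test_that("k = 1 keys reduce to a coprime scalar and its inverse", {
  keys <- rsa_keygen(20, 1, seed = 3)
  a <- keys$public$A[1, 1]
  expect_equal(heartledger:::.gcd_u64(a, keys$public$n), 1)
  expect_equal(heartledger:::.mod_mul(a, keys$private$A_inv[1, 1],
                                      keys$public$n), 1)
})

test_that("byte codec round-trips and is deterministic", {
  keys <- rsa_keygen(32, 2, seed = 9)
  set.seed(21)
  for (i in 1:50) {
    rec <- random_raw(sample(1:60, 1))
    blocks <- encode_record(rec, keys$public)
    expect_true(all(unlist(blocks) < keys$public$n))
    expect_true(all(lengths(blocks) == keys$public$k))
    expect_identical(decode_record(blocks, keys$public), rec)
  }
  rec <- as.raw(2)
  b1 <- encode_record(rec, keys$public)
  expect_identical(b1, encode_record(rec, keys$public))
  expect_equal(b1[[1]][1], 1)  # length prefix = 1 byte
  expect_error(encode_record(raw(0), keys$public), "empty")
})

test_that("full record round trip holds across k and key sizes, chained or not", {
  set.seed(31)
  for (bits in c(24, 32, 40)) for (kk in 1:3) {
    keys <- rsa_keygen(bits, kk, seed = bits + kk)
    for (i in 1:5) {
      rec <- random_raw(sample(1:40, 1))
      for (chain in c(FALSE, TRUE)) {
        ct <- encrypt_record(rec, keys$public, chain = chain)
        expect_identical(decrypt_record(ct, keys$private, chain = chain), rec)
      }
    }
  }
})

test_that("matrix mixing changes the ciphertext relative to plain RSA for k >= 2", {
  set.seed(7)
  found <- FALSE
  keys <- rsa_keygen(28, 2, seed = 77)
  pub_plain <- keys$public
  pub_plain$A <- diag(2)
  for (i in 1:10) {
    m <- list(floor(runif(2) * keys$public$n))
    if (!identical(rsa_encrypt(m, keys$public), rsa_encrypt(m, pub_plain)))
      found <- TRUE
  }
  expect_true(found)
})

test_that("keys and ciphertext survive JSON serialization", {
  keys <- rsa_keygen(36, 3, seed = 13)
  kf <- tempfile(fileext = ".json"); cf <- tempfile(fileext = ".json")
  write_keys(keys, kf)
  back <- read_keys(kf)
  expect_equal(back$public$n, keys$public$n)
  expect_equal(back$public$A, keys$public$A)
  expect_equal(back$private$A_inv, keys$private$A_inv)
  rec <- charToRaw("record: sensitive bytes")
  ct <- encrypt_record(rec, keys$public)
  write_cipher(ct, keys$public, cf)
  ct2 <- read_cipher(cf)
  expect_identical(decrypt_record(ct2, back$private), rec)
})
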