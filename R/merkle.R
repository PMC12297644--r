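#' Merkle trees and the hash-chain ledger
#'
#' SHA-256 throughout. Leaf nodes are hashed as `H(0x00 || leaf)` and
#' internal nodes as `H(0x01 || left || right)` -- the domain
#' separation prevents the classic internal-node-as-leaf forgery. An
#' odd node at any level is paired with itself (duplication
#' convention). Blocks carry the previous block's hash, the Merkle
#' root over their payload digests, a timestamp and a random nonce
#' tag; there is no proof-of-work.
#'
#' @name merkle_ledger
NULL

sha256_raw <- function(x) {
  h <- openssl::sha256(x)
  as.raw(h)
}

u_be <- function(x, width) {
  out <- raw(width)
  for (i in width:1) { out[i] <- as.raw(x %% 256); x <- x %/% 256 }
  out
}

leaf_hash <- function(leaf) sha256_raw(c(as.raw(0x00), leaf))
node_hash <- function(left, right) sha256_raw(c(as.raw(0x01), left, right))

#' Build a Merkle tree
#'
#' @param leaves list of raw vectors (the leaf byte strings).
#' @return list of levels, each a list of 32-byte digests; the last
#'   level holds the single root.
#' @export
merkle_tree <- function(leaves) {
  if (!length(leaves)) stopf("cannot build a Merkle tree from no leaves")
  level <- lapply(leaves, leaf_hash)
  levels <- list(level)
  while (length(level) > 1) {
    nxt <- vector("list", ceiling(length(level) / 2))
    for (i in seq_along(nxt)) {
      l <- level[[2 * i - 1]]
      r <- if (2 * i <= length(level)) level[[2 * i]] else l
      nxt[[i]] <- node_hash(l, r)
    }
    levels <- c(levels, list(nxt))
    level <- nxt
  }
  levels
}

#' Merkle root of a list of leaves
#' @inheritParams merkle_tree
#' @return 32-byte raw digest.
#' @export
merkle_root <- function(leaves) {
  lv <- merkle_tree(leaves)
  lv[[length(lv)]][[1]]
}

#' Merkle inclusion proof
#'
#' Returns the sibling path from leaf `index` to the root; an empty
#' proof for a single-leaf tree.
#'
#' @inheritParams merkle_tree
#' @param index leaf position (1-based).
#' @return list of steps, each `list(sibling = <digest>, side =
#'   "left"|"right")`.
#' @export
merkle_proof <- function(leaves, index) {
  if (index < 1 || index > length(leaves)) stopf("leaf index out of range")
  levels <- merkle_tree(leaves)
  proof <- list()
  pos <- index
  for (d in seq_len(length(levels) - 1)) {
    level <- levels[[d]]
    sib_pos <- if (pos %% 2 == 1) pos + 1 else pos - 1
    sib <- if (sib_pos <= length(level)) level[[sib_pos]] else level[[pos]]
    proof[[d]] <- list(sibling = sib,
                       side = if (pos %% 2 == 1) "right" else "left")
    pos <- (pos + 1) %/% 2
  }
  proof
}

#' Verify a Merkle inclusion proof
#'
#' @param leaf raw vector (the claimed leaf bytes).
#' @param index leaf position (1-based; kept for interface symmetry).
#' @param proof from [merkle_proof()].
#' @param root expected root digest.
#' @return `TRUE` iff the recomputed root equals `root`.
#' @export
merkle_verify <- function(leaf, index, proof, root) {
  h <- leaf_hash(leaf)
  for (step in proof) {
    h <- if (step$side == "right") node_hash(h, step$sibling)
         else node_hash(step$sibling, h)
  }
  identical(h, root)
}

serialize_block_header <- function(block) {
  payload <- block$payload
  buf <- c(u_be(block$index, 8), block$prev_hash, block$merkle_root,
           u_be(block$timestamp, 8), u_be(block$nonce, 8),
           u_be(length(payload), 4))
  for (p in payload) {
    id <- charToRaw(p$id)
    buf <- c(buf, u_be(length(id), 4), id, p$digest)
  }
  buf
}

block_hash <- function(block) sha256_raw(serialize_block_header(block))

#' Create an empty ledger chain
#' @return an object of class `ledger_chain` (empty block list).
#' @export
new_chain <- function() structure(list(), class = "ledger_chain")

#' Append a block of cipher records to the chain
#'
#' Computes each record's SHA-256 digest, the Merkle root over those
#' digests, links to the tip block's hash (the genesis block links to
#' 32 zero bytes), and stamps the block hash over the canonical
#' serialization (fixed field order, big-endian integers,
#' length-prefixed byte fields).
#'
#' @param chain a `ledger_chain`.
#' @param records named list: record id -> raw cipher bytes.
#' @param timestamp integer seconds (default current time).
#' @param nonce integer tag (default random; no proof-of-work).
#' @return the extended chain.
#' @export
append_block <- function(chain, records, timestamp = NULL, nonce = NULL) {
  stopifnot(inherits(chain, "ledger_chain"))
  if (!length(records)) stopf("cannot append an empty block")
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stopf("`records` must be a named list (record ids)")
  timestamp <- timestamp %||% as.integer(Sys.time())
  nonce <- nonce %||% floor(runif(1) * 2^31)
  payload <- lapply(names(records), function(id)
    list(id = id, digest = sha256_raw(records[[id]])))
  prev <- if (length(chain)) chain[[length(chain)]]$hash else raw(32)
  block <- list(index = length(chain) + 1L, prev_hash = prev,
                merkle_root = merkle_root(lapply(payload, `[[`, "digest")),
                timestamp = timestamp, nonce = nonce, payload = payload)
  block$hash <- block_hash(block)
  chain[[length(chain) + 1L]] <- block
  chain
}

#' Verify the integrity of a ledger chain
#'
#' Recomputes every block hash, the previous-hash linkage, and the
#' Merkle root over the stored payload digests.
#'
#' @param chain a `ledger_chain`.
#' @return list with `valid` and `first_bad_index` (NA when valid).
#' @export
verify_chain <- function(chain) {
  prev <- raw(32)
  for (i in seq_along(chain)) {
    b <- chain[[i]]
    ok <- identical(b$prev_hash, prev) &&
      b$index == i &&
      identical(b$merkle_root,
                merkle_root(lapply(b$payload, `[[`, "digest"))) &&
      identical(b$hash, block_hash(b))
    if (!ok) return(list(valid = FALSE, first_bad_index = i))
    prev <- b$hash
  }
  list(valid = TRUE, first_bad_index = NA_integer_)
}

#' @export
print.ledger_chain <- function(x, ...) {
  cat(sprintf("ledger chain: %d block(s), %d record reference(s)\n",
              length(x), sum(vapply(x, function(b) length(b$payload),
                                    integer(1)))))
  v <- verify_chain(x)
  cat("  integrity:", if (v$valid) "valid" else
    sprintf("INVALID at block %d", v$first_bad_index), "\n")
  invisible(x)
}

#' Audit stored cipher records against the ledger
#'
#' The third-party-auditor role: every payload reference is checked
#' against the storage map (record present, digest matches, Merkle
#' membership of the digest in the block root).
#'
#' @param chain a `ledger_chain`.
#' @param storage named list: record id -> raw cipher bytes.
#' @return list with `pass` (logical) and `failures` (data frame of
#'   block index, record id, reason).
#' @export
audit_chain <- function(chain, storage) {
  fails <- list()
  for (b in chain) {
    digests <- lapply(b$payload, `[[`, "digest")
    for (j in seq_along(b$payload)) {
      p <- b$payload[[j]]
      reason <- NULL
      if (is.null(storage[[p$id]])) reason <- "missing record"
      else if (!identical(sha256_raw(storage[[p$id]]), p$digest))
        reason <- "digest mismatch"
      else {
        proof <- merkle_proof(digests, j)
        h <- leaf_hash(p$digest)
        for (step in proof)
          h <- if (step$side == "right") node_hash(h, step$sibling)
               else node_hash(step$sibling, h)
        if (!identical(h, b$merkle_root)) reason <- "membership failure"
      }
      if (!is.null(reason))
        fails[[length(fails) + 1L]] <-
          data.frame(block = b$index, id = p$id, reason = reason)
    }
  }
  failures <- if (length(fails)) do.call(rbind, fails)
    else data.frame(block = integer(), id = character(),
                    reason = character())
  list(pass = nrow(failures) == 0, failures = failures)
}

log_entry_hash <- function(timestamp, block_index, verdict, prev_hash) {
  sha256_raw(c(u_be(timestamp, 8), u_be(block_index, 4),
               charToRaw(verdict), prev_hash))
}

#' Hash-chained audit log
#'
#' `generate_log()` appends one entry per audited block (or one
#' summary entry), each entry hash chained to the previous entry's
#' hash; `check_log()` revalidates the whole chain, returning `FALSE`
#' if any entry was edited.
#'
#' @param log existing log (list of entries) or `NULL` to start one.
#' @param report an audit report from [audit_chain()].
#' @param block_index block the verdict refers to (0 for a whole-chain
#'   verdict).
#' @param timestamp integer seconds.
#' @return `generate_log`: the extended log; `check_log`: logical.
#' @export
generate_log <- function(log = NULL, report, block_index = 0L,
                         timestamp = NULL) {
  log <- log %||% list()
  timestamp <- timestamp %||% as.integer(Sys.time())
  verdict <- if (report$pass) "pass" else "fail"
  prev <- if (length(log)) log[[length(log)]]$entry_hash else raw(32)
  entry <- list(timestamp = timestamp, block_index = as.integer(block_index),
                verdict = verdict, prev_hash = prev,
                entry_hash = log_entry_hash(timestamp, block_index, verdict,
                                            prev))
  log[[length(log) + 1L]] <- entry
  log
}

#' @rdname generate_log
#' @export
check_log <- function(log) {
  prev <- raw(32)
  for (e in log) {
    ok <- identical(e$prev_hash, prev) &&
      identical(e$entry_hash,
                log_entry_hash(e$timestamp, e$block_index, e$verdict,
                               e$prev_hash))
    if (!ok) return(FALSE)
    prev <- e$entry_hash
  }
  TRUE
}

hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")
unhex <- function(s) as.raw(strtoi(substring(s, seq(1, nchar(s), 2),
                                             seq(2, nchar(s), 2)), 16L))

#' Persist / load a ledger as JSON lines
#'
#' One block per line, digests hex-encoded.
#'
#' @param chain a `ledger_chain`.
#' @param path file path.
#' @export
write_chain <- function(chain, path) {
  lines <- vapply(chain, function(b) {
    jsonlite::toJSON(list(index = b$index, prev_hash = hex(b$prev_hash),
                          merkle_root = hex(b$merkle_root),
                          timestamp = b$timestamp, nonce = b$nonce,
                          payload = lapply(b$payload, function(p)
                            list(id = p$id, digest = hex(p$digest))),
                          hash = hex(b$hash)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Persist / load an audit log as JSON lines
#' @param log audit log from [generate_log()].
#' @param path file path.
#' @export
write_log <- function(log, path) {
  lines <- vapply(log, function(e)
    jsonlite::toJSON(list(timestamp = e$timestamp,
                          block_index = e$block_index, verdict = e$verdict,
                          prev_hash = hex(e$prev_hash),
                          entry_hash = hex(e$entry_hash)),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_log
#' @export
read_log <- function(path) {
  lapply(readLines(path), function(ln) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    list(timestamp = as.numeric(o$timestamp),
         block_index = as.integer(o$block_index), verdict = o$verdict,
         prev_hash = unhex(o$prev_hash), entry_hash = unhex(o$entry_hash))
  })
}

#' @rdname write_chain
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chain <- new_chain()
  for (ln in lines[nzchar(lines)]) {
    o <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    b <- list(index = as.integer(o$index), prev_hash = unhex(o$prev_hash),
              merkle_root = unhex(o$merkle_root),
              timestamp = as.numeric(o$timestamp),
              nonce = as.numeric(o$nonce),
              payload = lapply(o$payload, function(p)
                list(id = p$id, digest = unhex(p$digest))),
              hash = unhex(o$hash))
    chain[[length(chain) + 1L]] <- b
  }
  chain
}
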