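# Internal helpers: classed conditions, seeded RNG scopes, interval arithmetic.

# Classed errors so callers (and the CLI) can map failure modes to exit codes.
# class hierarchy: igsim_<what>_error < igsim_error < error
igsim_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "igsim_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

input_stop   <- function(msg) igsim_stop(msg, "igsim_input_error")
aligner_stop <- function(msg) igsim_stop(msg, "igsim_aligner_error")
internal_stop <- function(msg) igsim_stop(msg, "igsim_internal_error")

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
# A NULL seed leaves the global stream untouched (and consumed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    input_stop("'seed' must be a single non-missing number")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Intervals are 0-based half-open [start, end), kept as a 2-column matrix
# sorted by start with no overlaps (the "retained union" during
# de-replication).

# total overlap of [s, e) with a disjoint interval set
interval_overlap_len <- function(s, e, ivs) {
  if (nrow(ivs) == 0L) return(0)
  sum(pmax(0, pmin(e, ivs[, 2L]) - pmax(s, ivs[, 1L])))
}

# add [s, e) to a disjoint set, merging any touching/overlapping intervals
interval_union_add <- function(ivs, s, e) {
  m <- rbind(ivs, c(s, e))
  m <- m[order(m[, 1L]), , drop = FALSE]
  out_s <- m[1L, 1L]
  out_e <- m[1L, 2L]
  res <- matrix(numeric(0), ncol = 2L)
  if (nrow(m) > 1L) {
    for (k in 2L:nrow(m)) {
      if (m[k, 1L] <= out_e) {
        out_e <- max(out_e, m[k, 2L])
      } else {
        res <- rbind(res, c(out_s, out_e))
        out_s <- m[k, 1L]
        out_e <- m[k, 2L]
      }
    }
  }
  rbind(res, c(out_s, out_e))
}

interval_total_len <- function(ivs) {
  if (nrow(ivs) == 0L) return(0L)
  as.integer(sum(ivs[, 2L] - ivs[, 1L]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
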