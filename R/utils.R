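# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so package functions never
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Apportion a total sample count across classes proportionally
#'
#' Largest-remainder apportionment: each class receives floor of its exact
#' quota, remaining units go to the largest fractional remainders (ties by
#' class order). Guarantees the per-class counts sum to `m` and each is
#' within one unit of the exact proportional share.
#' @noRd
stratified_quota <- function(n_by_class, m) {
  exact <- m * n_by_class / sum(n_by_class)
  base <- floor(exact)
  rem <- m - sum(base)
  if (rem > 0) {
    take <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  # never ask for more than a class holds
  over <- base > n_by_class
  if (any(over)) {
    surplus <- sum(base[over] - n_by_class[over])
    base[over] <- n_by_class[over]
    room <- which(base < n_by_class)
    i <- 1
    while (surplus > 0 && length(room) > 0) {
      base[room[i]] <- base[room[i]] + 1
      surplus <- surplus - 1
      i <- if (i == length(room)) 1 else i + 1
      room <- which(base < n_by_class)
    }
  }
  stats::setNames(as.integer(base), names(n_by_class))
}

#' Derive a stage seed from a master seed
#'
#' Master seed fans out to per-stage seeds through fixed offsets so each
#' stage is independently reproducible. Kept within 32-bit integer range.
#' @noRd
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483629)
}
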