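# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

hp_stop <- function(...) stop(sprintf(...), call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min)
    hp_stop("'%s' must be a single integer >= %d (got %s)", name, min,
            paste(format(x), collapse = ","))
  as.integer(x)
}

assert_real <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    hp_stop("'%s' must be a single number in [%s, %s]", name, format(lo), format(hi))
  as.numeric(x)
}

assert_range <- function(x, name, lo, hi) {
  if (length(x) != 2L || anyNA(x) || x[1] > x[2] || x[1] < lo || x[2] > hi)
    hp_stop("'%s' must be a length-2 increasing range within [%s, %s]",
            name, format(lo), format(hi))
  as.numeric(x)
}

# Lexicographically ordered unordered pair, as a 2-column character matrix row.
canonical_pair <- function(a, b) {
  swap <- a > b
  cbind(herb_a = ifelse(swap, b, a), herb_b = ifelse(swap, a, b))
}

# All C(n, 2) unordered pairs of `x`, lexicographic by (first, second).
all_pairs <- function(x) {
  x <- sort(unique(x))
  if (length(x) < 2L)
    return(data.frame(herb_a = character(), herb_b = character(),
                      stringsAsFactors = FALSE))
  idx <- utils::combn(length(x), 2L)
  data.frame(herb_a = x[idx[1L, ]], herb_b = x[idx[2L, ]],
             stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  p <- canonical_pair(a, b)
  paste(p[, 1L], p[, 2L], sep = "\x1f")
}

# Uniform integer draw(s) from an inclusive range, safe for degenerate
# ranges (avoids sample()'s length-1 numeric surprise).
sample_range <- function(range, n = 1L) {
  range[1L] + sample.int(range[2L] - range[1L] + 1L, n, replace = TRUE) - 1L
}

# Atomic write: run `writer(tmp)` then rename onto `path`.
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    hp_stop("failed to move temporary file onto '%s'", path)
  invisible(path)
}
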