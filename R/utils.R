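# Internal numerical and plumbing helpers.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable log(1 + e^x).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

relu <- function(x) pmax(x, 0)

# Softmax over rows of a matrix, numerically stabilized.
row_softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Auto-detect comma vs tab delimiter from the first line of a file.
detect_delim <- function(path) {
  line <- readLines(path, n = 1L, warn = FALSE)
  if (length(line) == 0L) stop("file is empty: ", path)
  n_tab <- lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE)))
  n_com <- lengths(regmatches(line, gregexpr(",", line, fixed = TRUE)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

# Write a data.frame as delimited text at full double precision (17
# significant digits survive a text round trip exactly).
write_delim_full <- function(df, path, sep = ",") {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
}

is_binary01 <- function(x) all(x %in% c(0, 1))
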