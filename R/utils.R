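#' @keywords internal
"_PACKAGE"

## Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so library functions never clobber
## user-level reproducibility.
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
  })
  set.seed(seed)
  force(code)
}

## stop() with a simple formatted message, no call
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, allow_zero = FALSE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == trunc(x) &&
    (x > 0 || (allow_zero && x >= 0))
}

is_fraction <- function(x, open_left = FALSE) {
  length(x) == 1L && is.numeric(x) && !is.na(x) &&
    x <= 1 && (x > 0 || (!open_left && x >= 0))
}

## Canonical undirected edge representation: from <= to lexicographically
canonical_edges <- function(from, to) {
  swap <- from > to
  tmp <- from[swap]
  from[swap] <- to[swap]
  to[swap] <- tmp
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

## Sorted "from|to" keys for set comparisons between edge tables
edge_keys <- function(edges) {
  e <- canonical_edges(edges$from, edges$to)
  sort(paste(e$from, e$to, sep = "|"))
}

read_tsv_base <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

write_tsv_base <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## Matrix TSV with the row-id in the first column
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  write_tsv_base(df, path)
}

read_matrix_tsv <- function(path) {
  df <- read_tsv_base(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

## Dense rank of x in decreasing order: the largest value has rank 1 and
## ties share a rank, with no gaps (rank k+1 follows k).
dense_rank_desc <- function(x) {
  match(x, sort(unique(x), decreasing = TRUE))
}
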