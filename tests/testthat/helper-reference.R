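# Naive reference implementations, independent of the package internals:
# literal substring comparison for cores (maximality by containment
# filtering, not extension) and an O(n^2) double loop for pairing.

naive_cores <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  rows <- list()
  sub <- function(i, j) substr(seq, i, j)
  if (n >= 5) {
    for (i in 1:(n - 4)) {
      w <- sub(i, i + 4)
      if (w == "TTGAC")
        rows[[length(rows) + 1L]] <- c(i, i + 4L, "+")
      if (w == "GTCAA")
        rows[[length(rows) + 1L]] <- c(i, i + 4L, "-")
    }
  }
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      w <- sub(i, i + 3)
      if (w == "TGAC") rows[[length(rows) + 1L]] <- c(i, i + 3L, "+")
      if (w == "GTCA") rows[[length(rows) + 1L]] <- c(i, i + 3L, "-")
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  out <- data.frame(start = as.integer(vapply(rows, `[`, "", 1)),
                    end = as.integer(vapply(rows, `[`, "", 2)),
                    strand = vapply(rows, `[`, "", 3))
  # drop a 4-mer hit contained in a same-strand 5-mer hit
  is5 <- out$end - out$start == 4L
  keep <- rep(TRUE, nrow(out))
  for (k in which(!is5)) {
    contained <- is5 & out$strand == out$strand[k] &
      out$start <= out$start[k] & out$end >= out$end[k]
    if (any(contained)) keep[k] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

naive_dyads <- function(seq, max_linker) {
  cores <- naive_cores(seq)
  n <- nrow(cores)
  rows <- list()
  if (n >= 2) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        linker <- cores$start[b] - cores$end[a] - 1L
        if (linker >= 0L && linker <= max_linker)
          rows[[length(rows) + 1L]] <-
            c(cores$start[a], cores$start[b], linker)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(left = integer(), right = integer(),
                      linker = integer()))
  out <- data.frame(left = as.integer(vapply(rows, `[`, 0, 1)),
                    right = as.integer(vapply(rows, `[`, 0, 2)),
                    linker = as.integer(vapply(rows, `[`, 0, 3)))
  out[order(out$left, out$right), , drop = FALSE]
}

rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

all_kmers <- function(n) {
  g <- do.call(expand.grid,
               c(rep(list(c("A", "C", "G", "T")), n),
                 stringsAsFactors = FALSE))
  do.call(paste0, g)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
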