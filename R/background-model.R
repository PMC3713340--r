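#' Specify an i.i.d. background model for dyad occurrence statistics
#'
#' @param base_frequencies Numeric vector of four base probabilities in order
#'   A, C, G, T (names optional); must be non-negative and sum to 1 within
#'   1e-9.
#' @param window_length Window length in nt.
#' @param max_linker Maximum dyad linker length in nt (default 24).
#' @return A list of class \code{"background_spec"}.
#' @export
background_spec <- function(base_frequencies = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                            window_length, max_linker = 24L) {
  stopifnot(length(base_frequencies) == 4L, all(base_frequencies >= 0),
            window_length >= 1, max_linker >= 0)
  if (abs(sum(base_frequencies) - 1) > 1e-9)
    stop("base frequencies must sum to 1")
  names(base_frequencies) <- c("A", "C", "G", "T")
  structure(list(base_frequencies = base_frequencies,
                 window_length = as.integer(window_length),
                 max_linker = as.integer(max_linker)),
            class = "background_spec")
}

#' Expected number of 4-mer core match positions in a random window
#'
#' Linearity-of-expectation count of positions matching TGAC (plus strand) or
#' GTCA (core on the minus strand) in an i.i.d. window. Maximal extension is
#' ignored here (this counts 4-mer match positions, not maximal hits); both
#' 4-mers use each base once, so each has match probability
#' \eqn{p_A p_C p_G p_T}.
#'
#' @param spec A \code{\link{background_spec}}.
#' @return Expected count, \code{2 (L - 3) p_A p_C p_G p_T} (0 when L < 4).
#' @examples
#' expected_core_sites(background_spec(window_length = 8))  # 5/128
#' @export
expected_core_sites <- function(spec) {
  stopifnot(inherits(spec, "background_spec"))
  L <- spec$window_length
  if (L < 4L) return(0)
  2 * (L - 3) * prod(spec$base_frequencies)
}

# Transition matrix of the exact dyad-occurrence DP.
#
# One automaton step per base. The automaton node tracks progress toward the
# two 4-mer core words (TGAC on the plus strand, GTCA on the minus strand) the
# way an Aho-Corasick machine would, with two refinements that make the DP
# agree exactly with the scanner's maximal-core geometry:
#   * nodes on the T-G-A path carry a flag saying whether the base preceding
#     the initial T was itself a T, because a completed TGAC preceded by T is
#     the maximal 5-mer TTGAC whose start -- and hence its linker to the
#     previous core -- is one base further left;
#   * a completed GTCA enters a one-step lookahead node, because a following A
#     extends it to GTCAA whose end -- the origin for the next linker -- is
#     one base further right.
# Alongside the node, the state carries d = (positions since the end of the
# most recent maximal core), capped at max_linker + 6 (beyond which no linker
# can qualify), or NONE before the first core. Since maximal cores can never
# overlap, the most recent core always gives the shortest candidate linker,
# so tracking one distance suffices. When a core completes with a qualifying
# linker (0 <= linker <= max_linker) the chain is absorbed into an accepting
# state.
.dyad_dp_matrix <- function(base_frequencies, max_linker) {
  p <- stats::setNames(as.numeric(base_frequencies), c("A", "C", "G", "T"))
  K <- as.integer(max_linker)
  Dcap <- K + 6L
  nodes <- c("root", "T0", "T1", "TG0", "TG1", "TGA0", "TGA1",
             "G", "GT", "GTC", "GTCAdone")
  nd <- Dcap + 2L                     # d slot: 1 = NONE, k + 2 = (d == k)
  sid <- function(node, di) (match(node, nodes) - 1L) * nd + di
  ACCEPT <- length(nodes) * nd + 1L
  S <- ACCEPT
  goto <- list(
    root = c(A = "root", C = "root", G = "G", T = "T0"),
    T0   = c(A = "root", C = "root", G = "TG0", T = "T1"),
    T1   = c(A = "root", C = "root", G = "TG1", T = "T1"),
    TG0  = c(A = "TGA0", C = "root", G = "G", T = "GT"),
    TG1  = c(A = "TGA1", C = "root", G = "G", T = "GT"),
    TGA0 = c(A = "root", C = "!TGAC0", G = "G", T = "T0"),
    TGA1 = c(A = "root", C = "!TGAC1", G = "G", T = "T0"),
    G    = c(A = "root", C = "root", G = "G", T = "GT"),
    GT   = c(A = "root", C = "GTC", G = "TG0", T = "T1"),
    GTC  = c(A = "!GTCA", C = "root", G = "G", T = "T0"))
  M <- matrix(0, S, S)
  for (node in nodes) {
    for (di in seq_len(nd)) {
      s <- sid(node, di)
      for (b in c("A", "C", "G", "T")) {
        if (node == "GTCAdone") {
          # lookahead after a completed GTCA: an A extends it to GTCAA,
          # shifting the core end (d origin) one base right
          t <- switch(b,
                      A = sid("root", 0L + 2L),
                      C = sid("root", 1L + 2L),
                      G = sid("G", 1L + 2L),
                      T = sid("T0", 1L + 2L))
        } else {
          nx <- goto[[node]][[b]]
          if (nx == "!TGAC0" || nx == "!TGAC1") {
            ext <- if (nx == "!TGAC1") 1L else 0L
            if (di == 1L) {
              t <- sid("root", 0L + 2L)          # first core seen
            } else {
              dat <- min(di - 2L + 1L, Dcap)     # d at the completing base
              linker <- dat - 4L - ext           # maximal-core linker
              t <- if (linker >= 0L && linker <= K) ACCEPT
                   else sid("root", 0L + 2L)
            }
          } else if (nx == "!GTCA") {
            if (di == 1L) {
              t <- sid("GTCAdone", 1L)
            } else {
              dat <- min(di - 2L + 1L, Dcap)
              linker <- dat - 4L                 # minus-strand start is fixed
              t <- if (linker >= 0L && linker <= K) ACCEPT
                   else sid("GTCAdone", 1L)
            }
          } else {
            di2 <- if (di == 1L) 1L else min(di + 1L, Dcap + 2L)
            t <- sid(nx, di2)
          }
        }
        M[s, t] <- M[s, t] + p[[b]]
      }
    }
  }
  M[ACCEPT, ACCEPT] <- 1
  list(M = M, start = sid("root", 1L), accept = ACCEPT)
}

#' Exact probability that a random window contains a tandem dyad
#'
#' Computes, by dynamic programming over window positions, the exact
#' probability that an i.i.d. random window of the given length and base
#' composition contains at least one dyad element under the scanner's
#' definition (maximal cores on either strand, linker between 0 and
#' \code{max_linker} nt). The DP state couples a pattern-matching automaton
#' for the core words with the capped distance since the most recent core
#' end, and models maximal-core extension exactly, so it agrees with
#' exhaustive enumeration at any window length. Deterministic.
#'
#' @param spec A \code{\link{background_spec}}.
#' @return A probability in [0, 1]. Windows shorter than 8 nt (the shortest
#'   possible dyad) give exactly 0.
#' @examples
#' # in 8 nt only the four core-core concatenations contain a dyad:
#' dyad_probability(background_spec(window_length = 8))  # 4 / 4^8
#' @export
dyad_probability <- function(spec) {
  stopifnot(inherits(spec, "background_spec"))
  L <- spec$window_length
  if (L < 8L) return(0)
  dp <- .dyad_dp_matrix(spec$base_frequencies, spec$max_linker)
  v <- numeric(nrow(dp$M))
  v[dp$start] <- 1
  for (i in seq_len(L)) v <- as.vector(v %*% dp$M)
  v[dp$accept]
}

#' Monte-Carlo dyad occurrence rate
#'
#' Fraction of seeded random i.i.d. windows in which the scanner finds at
#' least one dyad; a stochastic cross-check of \code{\link{dyad_probability}}.
#'
#' @param spec A \code{\link{background_spec}}.
#' @param n_sims Number of simulated windows (>= 1).
#' @param seed Integer seed.
#' @return The observed fraction in [0, 1].
#' @export
simulate_dyad_rate <- function(spec, n_sims, seed = NULL) {
  stopifnot(inherits(spec, "background_spec"), n_sims >= 1)
  L <- spec$window_length
  K <- spec$max_linker
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    hits <- vapply(seq_len(n_sims), function(i) {
      w <- paste(sample(bases, L, replace = TRUE,
                        prob = spec$base_frequencies), collapse = "")
      cores <- find_cores(w)
      n <- nrow(cores)
      if (n < 2L) return(FALSE)
      # cores never overlap, so the shortest linker is between consecutive
      # cores; a dyad exists iff some consecutive gap is within the cap
      any(cores$start[-1L] - cores$end[-n] - 1L <= K)
    }, logical(1))
    mean(hits)
  })
}

#' Exhaustive brute-force dyad occurrence probability
#'
#' Enumerates every sequence of length \code{n} over A/C/G/T (in compiled
#' code, a literal re-scan of each sequence, independent of the DP) and
#' returns the total probability of the sequences containing at least one
#' dyad. Exact; feasible up to n = 14.
#'
#' @param n Window length (1..14).
#' @param base_frequencies Base probabilities in order A, C, G, T.
#' @param max_linker Maximum linker length in nt.
#' @return A probability in [0, 1].
#' @export
dyad_rate_exhaustive <- function(n, base_frequencies = rep(0.25, 4),
                                 max_linker = 24L) {
  .dyad_rate_exhaustive(as.integer(n), as.numeric(base_frequencies),
                        as.integer(max_linker))
}

#' Summary report of background occurrence statistics
#'
#' @param spec A \code{\link{background_spec}}.
#' @return One-row data frame: window length, max linker, base frequencies,
#'   expected 4-mer core sites, and the exact probability of at least one
#'   dyad.
#' @export
background_report <- function(spec) {
  stopifnot(inherits(spec, "background_spec"))
  data.frame(window_length = spec$window_length,
             max_linker = spec$max_linker,
             freq_A = spec$base_frequencies[["A"]],
             freq_C = spec$base_frequencies[["C"]],
             freq_G = spec$base_frequencies[["G"]],
             freq_T = spec$base_frequencies[["T"]],
             expected_core_sites = expected_core_sites(spec),
             dyad_probability = dyad_probability(spec))
}
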