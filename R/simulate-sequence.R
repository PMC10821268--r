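#' Generate a DNA sequence with planted G-quadruplex motifs
#'
#' The background is sampled approximately uniformly over A/C/G/T with G
#' and C runs capped at length 2, so default window scanning finds no
#' spurious hits. Each planted motif is a canonical four-tract
#' quadruplex-forming pattern `GGG N1-4 GGG N1-4 GGG N1-4 GGG` (spacers
#' from A/T), which guarantees a super-threshold scoring window by
#' construction. On a circular backbone with at least two planted motifs,
#' the first motif straddles the origin so wrap-around scanning is
#' exercised.
#'
#' @param seed integer seed.
#' @param length total sequence length (>= 100).
#' @param circular logical flag.
#' @param n_planted number of motifs to plant (>= 0).
#' @return A list with `seq` (a [circular_sequence]) and `truth` (list
#'   with `planted_g4_intervals`, a data.frame of 1-based inclusive
#'   `start`, `end`, `strand`; `end < start` marks an origin-straddling
#'   interval).
#' @examples
#' sim <- simulate_g4_sequence(seed = 1, length = 2000, n_planted = 2)
#' sim$truth$planted_g4_intervals
#' @export
simulate_g4_sequence <- function(seed = 1L, length = 5000L, circular = TRUE,
                                 n_planted = 3L) {
  if (!is_count(length, min = 100L)) stopf("'length' must be an integer >= 100")
  if (!is_count(n_planted, min = 0L)) stopf("'n_planted' must be >= 0")
  L <- as.integer(length)

  with_seed(seed, {
    # background with G/C runs capped at 2
    bases <- character(L)
    alphabet <- c("A", "C", "G", "T")
    for (i in seq_len(L)) {
      avoid <- if (i > 2L && bases[i - 1L] == bases[i - 2L] &&
                   bases[i - 1L] %in% c("G", "C")) bases[i - 1L] else NULL
      pool <- setdiff(alphabet, avoid)
      bases[i] <- pool[sample.int(length(pool), 1L)]
    }

    motifs <- character(n_planted)
    widths <- integer(n_planted)
    if (n_planted > 0L) {
      for (j in seq_len(n_planted)) {
        spacers <- vapply(1:3, function(.)
          paste(sample(c("A", "T"), sample(1:4, 1L), TRUE), collapse = ""),
          character(1L))
        motifs[j] <- paste0("GGG", spacers[1L], "GGG", spacers[2L],
                            "GGG", spacers[3L], "GGG")
        widths[j] <- nchar(motifs[j])
      }
      # placement with >= 30 bases of clearance between motifs
      gap <- 30L
      starts <- integer(n_planted)
      first <- 1L
      if (circular && n_planted >= 2L) {
        # straddle the origin: start so that roughly half wraps
        starts[1L] <- L - widths[1L] %/% 2L
        first <- 2L
      }
      occupied <- if (first == 2L) {
        c(seq(starts[1L] - gap, L), seq_len((starts[1L] + widths[1L] - 1L) %% L + gap))
      } else integer(0L)
      for (j in seq(from = first, length.out = n_planted - first + 1L)) {
        ok_pos <- setdiff(seq_len(L - widths[j] - gap), occupied)
        ok_pos <- ok_pos[ok_pos > gap]
        if (!base::length(ok_pos)) {
          stopf("cannot place motif %d without overlap; increase 'length'", j)
        }
        starts[j] <- ok_pos[sample.int(base::length(ok_pos), 1L)]
        occupied <- c(occupied,
                      seq(starts[j] - gap - widths[j], starts[j] + widths[j] + gap))
      }
      # splice motifs in, with non-G flanks so planted runs stay isolated
      for (j in seq_len(n_planted)) {
        chars <- strsplit(motifs[j], "")[[1L]]
        pos <- ((starts[j] - 1L + seq_along(chars) - 1L) %% L) + 1L
        bases[pos] <- chars
        before <- ((starts[j] - 2L) %% L) + 1L
        after <- ((starts[j] + widths[j] - 1L) %% L) + 1L
        if (bases[before] == "G") bases[before] <- "A"
        if (bases[after] == "G") bases[after] <- "A"
      }
    }
    truth <- data.frame(
      start = if (n_planted) starts else integer(0L),
      end = if (n_planted) ((starts + widths - 2L) %% L) + 1L else integer(0L),
      strand = rep("+", n_planted),
      stringsAsFactors = FALSE)
    list(seq = circular_sequence(paste(bases, collapse = ""),
                                 id = sprintf("synthetic_g4_seed%d", seed),
                                 circular = circular),
         truth = list(planted_g4_intervals = truth))
  })
}
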