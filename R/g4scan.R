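#' Circular (or linear) DNA sequence
#'
#' @param bases character string over A/C/G/T/N (case-insensitive).
#' @param id sequence identifier.
#' @param circular logical flag; positions are 1-based inclusive and, on a
#'   circular sequence, intervals with `end < start` wrap the origin.
#' @return An object of class `circular_sequence`.
#' @export
circular_sequence <- function(bases, id = "seq", circular = FALSE) {
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases)) {
    stopf("'bases' must be a non-empty character string")
  }
  bases <- toupper(bases)
  bad <- regmatches(bases, regexpr("[^ACGTN]", bases))
  if (length(bad)) stopf("illegal character '%s' in sequence", bad)
  structure(list(id = as.character(id), bases = bases,
                 circular = isTRUE(circular), length = nchar(bases)),
            class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  cat(sprintf("circular_sequence '%s': %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Per-base G-quadruplex propensity scores
#'
#' Run-capped G/C scoring: every base inside a run of `n` consecutive Gs
#' scores `+min(n, 4)`; a run of `n` Cs scores `-min(n, 4)`; A, T and N
#' score 0 (N breaks runs). On a circular sequence a run may wrap the
#' origin and is capped as one run.
#'
#' @param seq a [circular_sequence].
#' @return Integer vector of length `seq$length`.
#' @examples
#' base_scores(circular_sequence("GGGAA"))
#' @export
base_scores <- function(seq) {
  stopifnot(inherits(seq, "circular_sequence"))
  ch <- strsplit(seq$bases, "")[[1L]]
  r <- rle(ch)
  n_runs <- length(r$values)
  wrap_join <- seq$circular && n_runs > 1L && r$values[1L] == r$values[n_runs]
  lens <- r$lengths
  if (wrap_join) {
    joined <- lens[1L] + lens[n_runs]
    run_score <- function(v, len) {
      if (v == "G") min(len, 4L) else if (v == "C") -min(len, 4L) else 0L
    }
    per_run <- mapply(run_score, r$values, lens)
    per_run[1L] <- run_score(r$values[1L], joined)
    per_run[n_runs] <- per_run[1L]
    return(as.integer(rep(per_run, lens)))
  }
  per_run <- ifelse(r$values == "G", pmin(lens, 4L),
             ifelse(r$values == "C", -pmin(lens, 4L), 0L))
  as.integer(rep(per_run, lens))
}

#' Call G-quadruplex-prone sites by sliding-window scanning
#'
#' Windows of `window` bases (step 1) whose mean base score has absolute
#' value at least `threshold` are merged when they overlap, separately for
#' the two signs. A merged interval is reported once with strand `+` when
#' the signal is G-rich on the given strand and `-` when C-rich (the
#' quadruplex lies on the complement). On circular input, windows wrap the
#' origin and a hit spanning the origin is reported once with
#' `end < start`.
#'
#' @param seq a [circular_sequence].
#' @param window window size in bases.
#' @param threshold minimum absolute window mean.
#' @return A data.frame of hits with columns `start`, `end` (1-based
#'   inclusive; `end < start` marks a wrapping hit), `strand` and `score`
#'   (mean of the merged qualifying windows' mean scores, so
#'   `|score| >= threshold` always holds).
#' @export
call_hits <- function(seq, window = 25L, threshold = 1.2) {
  stopifnot(inherits(seq, "circular_sequence"))
  L <- seq$length
  if (!is_count(window) || window > L) {
    stopf("'window' must be an integer in [1, %d]", L)
  }
  w <- as.integer(window)
  s <- base_scores(seq)
  if (seq$circular) {
    ext <- c(s, s[seq_len(w - 1L)])
    n_win <- L
  } else {
    ext <- s
    n_win <- L - w + 1L
  }
  cs <- cumsum(c(0, ext))
  means <- (cs[(seq_len(n_win)) + w] - cs[seq_len(n_win)]) / w

  empty <- data.frame(start = integer(0L), end = integer(0L),
                      strand = character(0L), score = numeric(0L),
                      stringsAsFactors = FALSE)
  out <- empty
  for (sign_dir in c(1, -1)) {
    qual <- which(sign_dir * means >= threshold)
    if (!length(qual)) next
    # group windows whose intervals [i, i+w-1] overlap
    brk <- c(0L, which(diff(qual) > w - 1L), length(qual))
    groups <- mapply(function(a, b) qual[(a + 1L):b],
                     head(brk, -1L), tail(brk, -1L), SIMPLIFY = FALSE)
    iv <- do.call(rbind, lapply(groups, function(g) {
      # extended coordinates; score = mean of the qualifying windows' means,
      # so |score| >= threshold by construction
      c(start = min(g), end = max(g) + w - 1L, score = mean(means[g]),
        nq = length(g))
    }))
    if (seq$circular && nrow(iv) > 1L) {
      # the last group may wrap past the origin and overlap the first
      last <- nrow(iv)
      if (iv[last, "end"] > L && iv[last, "end"] - L >= iv[1L, "start"]) {
        n1 <- iv[1L, "nq"]
        n2 <- iv[last, "nq"]
        iv[1L, "score"] <- (n1 * iv[1L, "score"] + n2 * iv[last, "score"]) /
          (n1 + n2)
        iv[1L, "nq"] <- n1 + n2
        iv[1L, "start"] <- iv[last, "start"] - L
        iv <- iv[-last, , drop = FALSE]
      }
    }
    for (k in seq_len(nrow(iv))) {
      a <- iv[k, "start"]
      b <- iv[k, "end"]
      if (b - a + 1L >= L) {    # degenerate: signal covers the whole circle
        a <- 1L
        b <- L
      }
      out <- rbind(out, data.frame(
        start = as.integer(((a - 1L) %% L) + 1L),
        end = as.integer(((b - 1L) %% L) + 1L),
        strand = if (sign_dir > 0) "+" else "-",
        score = iv[k, "score"], stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Length of a (possibly origin-wrapping) interval on a circle
#'
#' Non-wrapping intervals (`start <= end`) count fully inclusively:
#' `end - start + 1`. Wrapping intervals (`start > end`) use the
#' one-endpoint-exclusive convention `(L - start) + end`, which counts the
#' origin once; this is the convention under which the mitochondrial
#' D-loop amplicon 16,067..644 on the 16,569-bp circle measures 1,146 bp.
#'
#' @param start,end 1-based positions in `[1, L]`.
#' @param L circle length.
#' @return Integer length in base pairs.
#' @examples
#' circular_interval_length(16067, 644, 16569)  # 1146
#' @export
circular_interval_length <- function(start, end, L) {
  if (!is_count(start) || !is_count(end) || !is_count(L) ||
      start > L || end > L) {
    stopf("positions must be integers in [1, L]")
  }
  if (start <= end) as.integer(end - start + 1L)
  else as.integer((L - start) + end)
}

#' Extract a region from a (circular) sequence
#'
#' Returns the bases from `start` to `end`, both inclusive, wrapping the
#' origin when `start > end` on a circular sequence.
#'
#' @param seq a [circular_sequence].
#' @param start,end 1-based inclusive positions.
#' @return A character string (linear sequence).
#' @examples
#' region_extract(circular_sequence("ACGT", circular = TRUE), 4, 1)  # "TA"
#' @export
region_extract <- function(seq, start, end) {
  stopifnot(inherits(seq, "circular_sequence"))
  L <- seq$length
  if (!is_count(start) || !is_count(end) || start > L || end > L) {
    stopf("positions must be integers in [1, %d]", L)
  }
  if (start <= end) {
    substr(seq$bases, start, end)
  } else {
    if (!seq$circular) {
      stopf("wrap-around extraction requested on a linear sequence")
    }
    paste0(substr(seq$bases, start, L), substr(seq$bases, 1L, end))
  }
}

FEATURE_CLASSES <- c("protein_coding", "rRNA", "tRNA", "D_loop",
                     "other_noncoding")

#' Read a feature table (BED-like TSV, 1-based inclusive)
#'
#' Columns: `name`, `start`, `end`, `strand`, `class`. Wrap-around
#' intervals (`end < start`) are allowed for circular genomes.
#'
#' @param path path to the TSV file.
#' @param L optional sequence length for coordinate validation.
#' @return A data.frame of features.
#' @export
read_features <- function(path, L = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "start", "end", "strand", "class")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) stopf("feature table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  bad <- setdiff(unique(tab$class), FEATURE_CLASSES)
  if (length(bad)) stopf("unknown feature class '%s'", bad[1L])
  if (!is.null(L) && any(tab$start < 1L | tab$start > L |
                         tab$end < 1L | tab$end > L)) {
    stopf("feature coordinates outside [1, %d]", L)
  }
  tab[, need]
}

#' Bundled human mitochondrial genome feature table
#'
#' Gene coordinates of the 16,569-bp human mitochondrial genome in rCRS
#' numbering: 13 protein-coding genes, 2 rRNAs, 22 tRNAs and the D-loop
#' control interval 16,067..644 (wrapping the origin).
#'
#' @return A data.frame of features (see [read_features()]).
#' @export
mtdna_features <- function() {
  read_features(system.file("extdata", "mtdna_features.tsv",
                            package = "mitoflux", mustWork = TRUE),
                L = 16569L)
}

#' Length of the rCRS mitochondrial genome
#' @return 16569L
#' @export
mtdna_length <- function() 16569L

midpoint_circ <- function(start, end, L) {
  span <- if (end >= start) end - start + 1L else L - start + 1L + end
  ((start - 1L + (span - 1L) %/% 2L) %% L) + 1L
}

in_feature_circ <- function(pos, fstart, fend) {
  if (fstart <= fend) pos >= fstart & pos <= fend
  else pos >= fstart | pos <= fend
}

#' Assign hits to genome features and summarise by class
#'
#' Each hit takes the class of the first feature (in table order) that
#' contains its midpoint, with circular containment for wrap-around
#' features; midpoints inside no feature count as `other_noncoding`.
#'
#' @param hits a data.frame from [call_hits()].
#' @param features a feature table from [read_features()].
#' @param L sequence length (defaults to the mitochondrial genome).
#' @return A list of class `hit_summary`: `n_total`, per-class counts
#'   (`class_counts`), `fraction_protein_coding`, `fraction_noncoding`
#'   (D_loop + other_noncoding), `fraction_of_noncoding_in_dloop`,
#'   `n_in_dloop`, and `assignment` (the per-hit classes).
#' @export
annotate_hits <- function(hits, features, L = mtdna_length()) {
  if (nrow(hits) &&
      (any(hits$start < 1L | hits$start > L | hits$end < 1L | hits$end > L))) {
    stopf("hit outside [1, %d]", L)
  }
  classes <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    mid <- midpoint_circ(hits$start[i], hits$end[i], L)
    hit_class <- "other_noncoding"
    for (f in seq_len(nrow(features))) {
      if (in_feature_circ(mid, features$start[f], features$end[f])) {
        hit_class <- features$class[f]
        break
      }
    }
    classes[i] <- hit_class
  }
  n <- nrow(hits)
  counts <- stats::setNames(
    vapply(FEATURE_CLASSES, function(cl) sum(classes == cl), integer(1L)),
    FEATURE_CLASSES)
  n_noncoding <- counts[["D_loop"]] + counts[["other_noncoding"]]
  structure(list(
    n_total = n,
    class_counts = counts,
    fraction_protein_coding = if (n) counts[["protein_coding"]] / n else 0,
    fraction_noncoding = if (n) n_noncoding / n else 0,
    fraction_of_noncoding_in_dloop =
      if (n_noncoding) counts[["D_loop"]] / n_noncoding else 0,
    n_in_dloop = counts[["D_loop"]],
    assignment = classes), class = "hit_summary")
}

#' @export
print.hit_summary <- function(x, ...) {
  cat(sprintf("hit_summary: %d hits\n", x$n_total))
  cat(sprintf("  protein coding: %.1f%%\n", 100 * x$fraction_protein_coding))
  cat(sprintf("  non-coding: %.1f%% (of which %.1f%% in the D-loop; n = %d)\n",
              100 * x$fraction_noncoding,
              100 * x$fraction_of_noncoding_in_dloop, x$n_in_dloop))
  invisible(x)
}

#' Scan an rCRS mitochondrial genome FASTA and summarise D-loop content
#'
#' Runs [call_hits()] on a user-supplied human mitochondrial genome
#' sequence (circular, both strands via the signed score) and annotates
#' the hits with the bundled feature table. The sequence itself is not
#' bundled; supply a FASTA of NC_012920.1.
#'
#' @param fasta_path path to the rCRS FASTA file.
#' @param window,threshold scan parameters.
#' @return A list with `hits` and `summary` (a `hit_summary`).
#' @export
g4_benchmark_rcrs <- function(fasta_path, window = 25L, threshold = 1.2) {
  seqs <- read_fasta(fasta_path, circular = TRUE)
  seq <- seqs[[1L]]
  if (seq$length != mtdna_length()) {
    warnf("sequence length %d differs from the rCRS length %d",
          seq$length, mtdna_length())
  }
  hits <- call_hits(seq, window = window, threshold = threshold)
  list(hits = hits,
       summary = annotate_hits(hits, mtdna_features(), L = seq$length))
}

#' Write hits as TSV and BED
#'
#' The TSV keeps the package's 1-based inclusive coordinates; the BED
#' export converts to 0-based half-open at the boundary (wrapping hits are
#' split into two BED lines).
#'
#' @param hits data.frame from [call_hits()].
#' @param path output TSV path.
#' @param bed_path optional BED output path.
#' @param L sequence length (needed to split wrapping hits in BED).
#' @param seq_id sequence name for the BED chrom column.
#' @return Invisibly, the paths written.
#' @export
write_hits <- function(hits, path, bed_path = NULL, L = NULL,
                       seq_id = "seq") {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    rows <- list()
    for (i in seq_len(nrow(hits))) {
      s <- hits$start[i]; e <- hits$end[i]
      if (e >= s) {
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = seq_id, start = s - 1L, end = e,
                     name = sprintf("G4_%03d", i), score = hits$score[i],
                     strand = hits$strand[i])
      } else {
        if (is.null(L)) stopf("'L' is required to export wrapping hits as BED")
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = seq_id, start = s - 1L, end = L,
                     name = sprintf("G4_%03da", i), score = hits$score[i],
                     strand = hits$strand[i])
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = seq_id, start = 0L, end = e,
                     name = sprintf("G4_%03db", i), score = hits$score[i],
                     strand = hits$strand[i])
      }
    }
    bed <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0), score = numeric(0), strand = character(0))
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(c(path, bed_path))
}
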