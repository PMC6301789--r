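# default 21 bp GC-rich (~57%) curved motif: two helical turns (10 + 11 bp)
# of phased positive-roll (CC/CG/GG) vs negative-roll (AA/AT/TT) half-turns;
# chosen by maximizing the model's 73 bp intrinsic curvature over GC-rich
# candidates, the same design rule the curved constructs emulate
.GC_CURVED_MOTIF <- "CCCGGAATTCCCCGGAATTTC"

#' Deterministic synthetic DNA fixtures
#'
#' Generates the designed-sequence classes used throughout the package's
#' tests and examples, emulating the design rules of single-molecule
#' plectoneme constructs:
#'
#' * `"phased_tract"` -- a motif (default the A5 tract `"AAAAA"`) repeated at
#'   a fixed (possibly fractional) period, default 10.5 bp so that successive
#'   tracts stay in helical phase; gaps are filled with a cycling filler whose
#'   positive-roll steps are antiphase to the tract. Strongly curved.
#' * `"flat_random"` -- seeded uniform random sequence that never contains a
#'   homopolymer run of 4 or more. Flat on average.
#' * `"gc_rich_curved"` -- `n_repeats` copies of a GC-rich (~57%) curved unit
#'   (default 75 bp cut from a phased 21 bp motif).
#' * `"insert_in_backbone"` -- an insert (given, or generated from another
#'   kind) placed inside a flat random backbone; the returned string carries
#'   `insert_start`/`insert_end` attributes.
#'
#' The same spec and seed always produce the identical sequence; kinds that
#' draw random bases require an explicit `seed`.
#'
#' @param kind Fixture class (see above).
#' @param length Total length, bp (defaults per kind).
#' @param unit Tract motif (`phased_tract`) or curved unit (`gc_rich_curved`).
#' @param period Tract period, bp; may be fractional (tract j starts at
#'   `floor(j * period) + 1`).
#' @param n_repeats Number of tracts / unit copies.
#' @param filler Filler pattern cycled between tracts.
#' @param insert Insert sequence (`insert_in_backbone`).
#' @param insert_position 1-based start of the insert in the backbone.
#' @param backbone_length Backbone length, bp.
#' @param seed Integer seed (mandatory for random kinds).
#' @return A DNA string; for `insert_in_backbone` with attributes
#'   `insert_start` and `insert_end`.
#' @examples
#' make_fixture("phased_tract", n_repeats = 7, length = 75)
#' @export
make_fixture <- function(kind = c("phased_tract", "flat_random",
                                  "insert_in_backbone", "gc_rich_curved"),
                         length = NULL, unit = NULL, period = 10.5,
                         n_repeats = NULL, filler = "CGGGC", insert = NULL,
                         insert_position = NULL, backbone_length = 10000L,
                         seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    phased_tract = {
      unit <- unit %||% "AAAAA"
      if (period < nchar(unit)) {
        abort(paste0("`period` (", period, ") must be at least the motif ",
                     "length (", nchar(unit), ")"))
      }
      if (is.null(n_repeats) && is.null(length)) {
        abort("give `n_repeats` and/or `length` for phased_tract")
      }
      n_repeats <- n_repeats %||% floor((length - nchar(unit)) / period + 1)
      length <- length %||% ceiling((n_repeats - 1) * period + nchar(unit))
      fill <- strsplit(filler, "")[[1]]
      base <- fill[(seq_len(length) - 1L) %% length(fill) + 1L]
      u <- strsplit(unit, "")[[1]]
      for (j in seq_len(n_repeats)) {
        at <- floor((j - 1) * period) + 1L
        if (at + nchar(unit) - 1L > length) break
        base[at:(at + nchar(unit) - 1L)] <- u
      }
      paste(base, collapse = "")
    },
    flat_random = {
      if (is.null(length)) abort("give `length` for flat_random")
      if (is.null(seed)) abort("random fixtures require an explicit `seed`")
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
      bases <- c("A", "C", "G", "T")
      out <- character(length)
      run <- 0L
      prev <- ""
      for (i in seq_len(length)) {
        pool <- if (run >= 3L) setdiff(bases, prev) else bases
        b <- sample(pool, 1L)
        run <- if (b == prev) run + 1L else 1L
        prev <- b
        out[i] <- b
      }
      paste(out, collapse = "")
    },
    gc_rich_curved = {
      n_repeats <- n_repeats %||% 8L
      unit <- unit %||% substr(strrep(.GC_CURVED_MOTIF, 4L), 1L, 75L)
      strrep(unit, n_repeats)
    },
    insert_in_backbone = {
      if (is.null(insert)) abort("give `insert` for insert_in_backbone")
      if (is.null(seed)) abort("random fixtures require an explicit `seed`")
      backbone <- make_fixture("flat_random", length = backbone_length,
                               seed = seed)
      li <- nchar(insert)
      at <- insert_position %||% (backbone_length %/% 2L - li %/% 2L)
      if (at < 1L || at + li - 1L > backbone_length) {
        abort("insert does not fit in the backbone at `insert_position`")
      }
      out <- paste0(substr(backbone, 1L, at - 1L), insert,
                    substr(backbone, at + li, backbone_length))
      structure(out, insert_start = at, insert_end = at + li - 1L)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sequences to a FASTA file
#'
#' @param seqs Character vector of sequences (names become record headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  set <- Biostrings::DNAStringSet(unlist(lapply(seqs, as.character)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
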