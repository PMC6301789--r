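# coerce a FASTA path / DNAStringSet / named character vector to a named
# character vector of sequences
.as_seq_set <- function(fasta) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta)) {
    set <- Biostrings::readDNAStringSet(fasta)
    if (length(set) == 0) abort(paste0("empty FASTA: ", fasta))
    seqs <- as.character(set)
    names(seqs) <- sub("\\s.*", "", names(set))
    return(seqs)
  }
  if (methods::is(fasta, "XStringSet")) {
    if (length(fasta) == 0) abort("empty sequence set")
    seqs <- as.character(fasta)
    names(seqs) <- sub("\\s.*", "", names(fasta))
    return(seqs)
  }
  if (methods::is(fasta, "XString")) fasta <- as.character(fasta)
  if (is.character(fasta)) {
    if (length(fasta) == 0) abort("empty sequence set")
    if (is.null(names(fasta))) {
      names(fasta) <- paste0("seq", seq_along(fasta))
    }
    return(fasta)
  }
  abort("`fasta` must be a FASTA path, a Biostrings set, or a character vector")
}

# W_tot for one (possibly long) sequence, evaluated in overlapping chunks so
# memory stays flat; results are independent of the chunk size because every
# model quantity only looks +/-65 bp around its center
.wtot_chunked <- function(seq_chr, params, tension, circular, chunk_size,
                          ambiguity = "error") {
  L <- nchar(seq_chr)
  m <- .SUPPORT_MARGIN
  if (L <= chunk_size) {
    path <- ground_state_path(seq_chr, params, circular, ambiguity)
    res <- .wtot_engine(path, params, tension)
    w <- rep(NA_real_, L)
    w[res$positions] <- res$w_tot
    return(w)
  }
  starts <- seq.int(1L, L, by = chunk_size)
  w <- rep(NA_real_, L)
  big <- strsplit(seq_chr, "")[[1]]
  for (a in starts) {
    b <- min(a + chunk_size - 1L, L)
    lo <- a - m
    hi <- b + m
    if (circular) {
      idx <- ((seq.int(lo, hi) - 1L) %% L) + 1L
      sub <- paste(big[idx], collapse = "")
      first <- lo
    } else {
      first <- max(1L, lo)
      sub <- paste(big[seq.int(first, min(L, hi))], collapse = "")
    }
    path <- ground_state_path(sub, params, circular = FALSE,
                              ambiguity = ambiguity)
    res <- .wtot_engine(path, params, tension)
    pos <- res$positions + first - 1L  # chunk-local -> chromosome coordinates
    keep <- pos >= a & pos <= b
    w[pos[keep]] <- res$w_tot[keep]
  }
  w
}

#' Scan a genome for plectoneme pinning strength
#'
#' Runs the density model over every record of a FASTA file (or sequence
#' set), producing per-chromosome per-base tracks of the total Boltzmann
#' weight, the plectoneme density (normalized to mean 1 per chromosome) and
#' the free-energy landscape. Long chromosomes are evaluated in overlapping
#' chunks; because the model is strictly local (+/-65 bp), the result is
#' independent of the chunking.
#'
#' @param fasta FASTA path, Biostrings `DNAStringSet`, or named character
#'   vector.
#' @param tension Tension, pN.
#' @param params A [dinuc_params()] set.
#' @param circular Logical, recycled or named per record; circular records
#'   wrap all windows (e.g. a bacterial chromosome).
#' @param chunk_size Evaluation chunk, bp.
#' @param ambiguity Non-ACGT handling; genomes with N runs need
#'   `"substitute"`.
#' @return A tibble of class `plectoneme_tracks`: `chrom`, `position`,
#'   `w_tot`, `density`, `free_energy`, `defined`.
#' @export
scan_genome <- function(fasta, tension = 3, params = dinuc_params(),
                        circular = FALSE, chunk_size = 20000L,
                        ambiguity = c("error", "substitute")) {
  ambiguity <- match.arg(ambiguity)
  seqs <- .as_seq_set(fasta)
  circ <- .match_flags(circular, names(seqs))
  rows <- lapply(names(seqs), function(nm) {
    L <- nchar(seqs[[nm]])
    if (L < .MIN_LENGTH) {
      abort(paste0("record '", nm, "' is ", L, " bp; minimum is ",
                   .MIN_LENGTH, " bp"))
    }
    w <- .wtot_chunked(seqs[[nm]], params, tension, circ[[nm]], chunk_size,
                       ambiguity)
    defined <- !is.na(w)
    tibble(chrom = nm, position = seq_len(L), w_tot = w,
           density = w / mean(w[defined]), free_energy = -log(w),
           defined = defined)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("plectoneme_tracks", class(tibble())),
            tension = tension, params_name = params$name, circular = circ)
}

.match_flags <- function(circular, chroms) {
  if (is.null(names(circular))) {
    circ <- rep_len(as.logical(circular), length(chroms))
    names(circ) <- chroms
  } else {
    circ <- stats::setNames(rep(FALSE, length(chroms)), chroms)
    circ[intersect(names(circular), chroms)] <-
      circular[intersect(names(circular), chroms)]
  }
  as.list(circ)
}

#' Read a table of transcription start sites
#'
#' Accepts either a 4-column TSV (`chromosome`, `position` 1-based, `strand`,
#' optional `name`) or BED6 (strand from column 6; the TSS is taken as the
#' interval start for `+` records and the interval end for `-` records,
#' converted to 1-based coordinates). `#` comment and `track` lines are
#' skipped.
#'
#' @param path File path.
#' @return A tibble: `chrom`, `position`, `strand`, `name`.
#' @export
read_tss_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#|^track|^browser", lines) & nzchar(trimws(lines))
  recs <- list()
  for (li in which(keep)) {
    tok <- strsplit(trimws(lines[li]), "[[:space:]]+")[[1]]
    if (length(tok) >= 6 &&
        !is.na(suppressWarnings(as.integer(tok[2]))) &&
        !is.na(suppressWarnings(as.integer(tok[3]))) &&
        tok[6] %in% c("+", "-")) {
      start0 <- as.integer(tok[2]); end <- as.integer(tok[3])
      pos <- if (tok[6] == "+") start0 + 1L else end
      recs[[length(recs) + 1]] <- tibble(chrom = tok[1], position = pos,
                                         strand = tok[6], name = tok[4])
    } else if (length(tok) >= 3 && tok[3] %in% c("+", "-") &&
               !is.na(suppressWarnings(as.integer(tok[2])))) {
      recs[[length(recs) + 1]] <- tibble(
        chrom = tok[1], position = as.integer(tok[2]), strand = tok[3],
        name = if (length(tok) >= 4) tok[4] else NA_character_)
    } else {
      abort(paste0("malformed TSS record at line ", li, " of ", path,
                   ": '", lines[li], "'"))
    }
  }
  if (length(recs) == 0) abort(paste0("no TSS records in ", path))
  dplyr::bind_rows(recs)
}

#' Strand-aware meta-profile around transcription start sites
#'
#' Extracts a window of the (unsmoothed) per-base track around every TSS,
#' reverses minus-strand windows so that negative offsets are always upstream
#' on the gene's strand, averages across sites (each site contributes once),
#' and smooths the mean with a centered 51 bp moving average. Sites outside
#' the track, or whose window is not fully defined, are dropped with a
#' message.
#'
#' @param tracks A `plectoneme_tracks` tibble from [scan_genome()].
#' @param tss A TSS tibble (see [read_tss_table()]).
#' @param halfwidth Window half-width, bp (offsets `-halfwidth:halfwidth`).
#' @param smooth_window Moving-average window, bp (odd).
#' @param value Track column to average: `"density"` or `"free_energy"`.
#' @return A tibble of class `plectoneme_metaprofile`: `offset`,
#'   `mean_raw`, `mean_density` (smoothed); attributes `n_sites`,
#'   `smoothing_window`, `value`.
#' @export
tss_metaprofile <- function(tracks, tss, halfwidth = 400L, smooth_window = 51L,
                            value = c("density", "free_energy")) {
  value <- match.arg(value)
  if (nrow(tss) == 0) abort("empty TSS table")
  if (smooth_window %% 2L == 0L) abort("`smooth_window` must be odd")
  circ <- attr(tracks, "circular")
  offs <- seq.int(-halfwidth, halfwidth)
  chroms <- split(tracks, tracks$chrom)
  win <- list()
  dropped <- 0L
  for (r in seq_len(nrow(tss))) {
    ch <- tss$chrom[r]; p <- tss$position[r]
    tr <- chroms[[ch]]
    if (is.null(tr) || p < 1L || p > nrow(tr)) {
      dropped <- dropped + 1L
      next
    }
    L <- nrow(tr)
    idx <- p + offs
    wrap <- isTRUE(circ[[ch]])
    if (wrap) {
      idx <- ((idx - 1L) %% L) + 1L
    } else if (idx[1] < 1L || idx[length(idx)] > L) {
      dropped <- dropped + 1L
      next
    }
    v <- tr[[value]][idx]
    if (anyNA(v)) {
      dropped <- dropped + 1L
      next
    }
    if (tss$strand[r] == "-") v <- rev(v)
    win[[length(win) + 1]] <- v
  }
  if (dropped > 0) {
    message(dropped, " TSS site(s) dropped (out of bounds or window not ",
            "fully defined)")
  }
  if (length(win) == 0) abort("no usable TSS site remains")
  m <- colMeans(do.call(rbind, win))
  kern <- rep(1 / smooth_window, smooth_window)
  num <- .conv_same(m, kern)
  den <- .conv_same(rep(1, length(m)), kern)
  sm <- num / den
  out <- tibble(offset = offs, mean_raw = m, mean_density = sm)
  structure(out, class = c("plectoneme_metaprofile", class(tibble())),
            n_sites = length(win), smoothing_window = smooth_window,
            value = value, halfwidth = halfwidth)
}

#' Export a per-base track as bedGraph
#'
#' Writes sorted, non-overlapping single-base records in the bedGraph
#' convention (0-based half-open intervals). Masked (undefined) positions
#' produce no records -- they are absent, never zero-filled.
#'
#' @param tracks A `plectoneme_tracks` or `plectoneme_profile` tibble (the
#'   latter is written as chromosome `"seq1"` unless `chrom` is given).
#' @param path Output path.
#' @param value Column to export.
#' @param chrom Chromosome name used for a bare profile.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(tracks, path, value = "density", chrom = "seq1") {
  if (!"chrom" %in% names(tracks)) tracks$chrom <- chrom
  v <- tracks[[value]]
  keep <- !is.na(v)
  df <- tracks[keep, ]
  df <- df[order(df$chrom, df$position), ]
  lines <- sprintf("%s\t%d\t%d\t%.10g", df$chrom, df$position - 1L,
                   df$position, df[[value]])
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-base bedGraph track written by [write_bedgraph()]
#'
#' @param path File path.
#' @return A tibble: `chrom`, `position` (1-based), `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^#|^track|^browser", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) abort(paste0("no records in ", path))
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    tok <- strsplit(trimws(lines[keep[j]]), "[[:space:]]+")[[1]]
    if (length(tok) < 4 || anyNA(suppressWarnings(as.numeric(tok[2:4])))) {
      abort(paste0("malformed bedGraph line ", keep[j], " of ", path))
    }
    out[[j]] <- tibble(chrom = tok[1],
                       position = as.integer(tok[3]),
                       value = as.numeric(tok[4]))
  }
  dplyr::bind_rows(out)
}

#' Export a per-base track as plain TSV
#'
#' @param tracks A `plectoneme_tracks` or `plectoneme_profile` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(tracks, path) {
  utils::write.table(as.data.frame(tracks), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV track written by [write_track_tsv()]
#'
#' @param path File path.
#' @return A `plectoneme_tracks` tibble.
#' @export
read_track_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!"chrom" %in% names(df)) df$chrom <- "seq1"
  if (!"defined" %in% names(df)) df$defined <- !is.na(df$density)
  structure(as_tibble(df), class = c("plectoneme_tracks", class(tibble())),
            circular = stats::setNames(
              as.list(rep(FALSE, length(unique(df$chrom)))),
              unique(df$chrom)))
}
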