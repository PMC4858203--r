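#' Read a 4-field spore contig CSV
#'
#' Reads the comma-separated contig format used for spore resequencing
#' datasets: one row per spore with (1) unique sequence identifier, (2) the
#' recorded total of C/T mutations, (3) the recorded total of G/A mutations,
#' and (4) the complete nucleotide sequence. Gzip-compressed files are
#' detected by the `.gz` suffix. Recorded counts are kept separate from any
#' counts recomputed by [callMutations()], so the two can be verified
#' against each other.
#'
#' @param path path to the CSV (optionally `.gz`).
#' @return data.frame with columns `id`, `n_CT_recorded`, `n_GA_recorded`,
#'   `seq` and logical `flagged` (TRUE when the sequence contains non-ACGT
#'   characters, with a warning). An empty file yields an empty data.frame
#'   with a warning.
#' @export
readS3Csv <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(id = character(0), n_CT_recorded = integer(0),
                      n_GA_recorded = integer(0), seq = character(0),
                      flagged = logical(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) {
    warning("empty contig CSV: ", path, call. = FALSE)
    return(empty)
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4)) {
    bad <- which(nf != 4)[1]
    stop("malformed row at line ", bad, " of ", path, ": expected 4 ",
         "comma-separated fields, found ", nf[bad], call. = FALSE)
  }
  m <- do.call(rbind, fields)
  counts <- suppressWarnings(cbind(as.integer(m[, 2]), as.integer(m[, 3])))
  if (anyNA(counts)) {
    bad <- which(rowSums(is.na(counts)) > 0)[1]
    stop("malformed row at line ", bad, " of ", path,
         ": mutation counts are not integers", call. = FALSE)
  }
  seqs <- toupper(m[, 4])
  flagged <- grepl("[^ACGT]", seqs)
  if (any(flagged)) {
    warning(sum(flagged), " record(s) contain non-ACGT characters and are ",
            "flagged", call. = FALSE)
  }
  data.frame(id = m[, 1], n_CT_recorded = counts[, 1],
             n_GA_recorded = counts[, 2], seq = seqs, flagged = flagged,
             stringsAsFactors = FALSE)
}

#' Write a 4-field spore contig CSV
#'
#' @param records data.frame with columns `id`, `n_CT_recorded` (or `n_CT`),
#'   `n_GA_recorded` (or `n_GA`) and `seq`.
#' @param path output path; a `.gz` suffix writes gzip-compressed output.
#' @return Invisibly, `path`.
#' @export
writeS3Csv <- function(records, path) {
  ct <- if ("n_CT_recorded" %in% names(records)) records$n_CT_recorded
        else records$n_CT
  ga <- if ("n_GA_recorded" %in% names(records)) records$n_GA_recorded
        else records$n_GA
  stopifnot(!is.null(ct), !is.null(ga),
            all(c("id", "seq") %in% names(records)))
  lines <- paste(records$id, ct, ga, records$seq, sep = ",")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Parse spore identifiers
#'
#' Splits identifiers of the form `"{RepeatID}{cross}_{spore}"` (RepeatID
#' alphabetic, e.g. `"XIF1_1"`) into their three parts.
#'
#' @param id character vector of spore identifiers.
#' @return data.frame with columns `repeatId`, `cross`, `spore`.
#' @export
parseSporeId <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z]+)([0-9]+)_([0-9]+)$", id))
  bad <- which(lengths(m) != 4)
  if (length(bad)) {
    stop("unparseable spore id: '", id[bad[1]], "'", call. = FALSE)
  }
  parts <- do.call(rbind, m)
  data.frame(repeatId = parts[, 2], cross = as.integer(parts[, 3]),
             spore = as.integer(parts[, 4]), stringsAsFactors = FALSE)
}

#' Write a pairwise reference/test alignment in ClustalW format
#'
#' Writes a two-sequence (gap-free, equal-length) alignment in ClustalW
#' layout: 60-column blocks with a conservation line marking identical
#' columns with `*`.
#'
#' @param cassette a [Cassette-class].
#' @param path output path.
#' @param ids character(2) sequence names (default reference/test labels
#'   built from the cassette id).
#' @return Invisibly, `path`.
#' @export
writeClustalwPair <- function(cassette, path, ids = NULL) {
  stopifnot(is(cassette, "Cassette"))
  if (is.null(ids)) {
    ids <- paste0(cassette@id, c("_ref", "_test"))
  }
  ids <- gsub("[[:space:]]", "_", ids)
  width <- max(nchar(ids)) + 3
  refc <- as.character(cassette@referenceCopy)
  tstc <- as.character(cassette@testCopy)
  cons <- paste(ifelse(cassette@homologyMask, "*", " "), collapse = "")
  lines <- c("CLUSTAL W multiple sequence alignment", "", "")
  for (start in seq(1, nchar(refc), by = 60)) {
    end <- min(start + 59, nchar(refc))
    lines <- c(lines,
      sprintf("%-*s%s", width, ids[1], substr(refc, start, end)),
      sprintf("%-*s%s", width, ids[2], substr(tstc, start, end)),
      sprintf("%-*s%s", width, "", substr(cons, start, end)),
      "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a pairwise reference/test alignment in ClustalW format
#'
#' Reads a two-sequence ClustalW alignment and derives the homology mask
#' from column-wise equality. Columns containing a gap in either sequence
#' are excluded from the returned (ungapped, reference-coordinate) mask and
#' their count is reported.
#'
#' @param path path to a ClustalW file with exactly two sequences.
#' @return `list(reference, test, mask, nGapColumns)`: the degapped
#'   [Biostrings::DNAString] sequences, the logical equality mask over
#'   gap-free columns, and the number of excluded gap columns.
#' @export
readClustalwPair <- function(path) {
  aln <- Biostrings::readDNAMultipleAlignment(path, format = "clustal")
  rows <- as.character(Biostrings::unmasked(aln))
  if (length(rows) != 2) {
    stop("expected exactly 2 sequences, found ", length(rows), call. = FALSE)
  }
  r1 <- strsplit(rows[1], "")[[1]]
  r2 <- strsplit(rows[2], "")[[1]]
  gap <- r1 == "-" | r2 == "-"
  if (any(gap)) {
    message(sum(gap), " gap column(s) excluded from the homology mask")
  }
  ref <- r1[!gap]
  tst <- r2[!gap]
  list(reference = .charsToDNAString(ref),
       test = .charsToDNAString(tst),
       mask = unname(ref == tst),
       nGapColumns = sum(gap))
}

#' Export a homology mask as BED
#'
#' Writes the maximal homologous runs of a cassette as BED features.
#' Internally everything is 1-based inclusive; the BED file follows the
#' format's 0-based half-open convention on write (handled by the exporter).
#'
#' @param cassette a [Cassette-class].
#' @param path output `.bed` path.
#' @param chrom sequence name for the BED records (default the cassette id).
#' @return Invisibly, `path`.
#' @export
writeMaskBed <- function(cassette, path, chrom = NULL) {
  stopifnot(is(cassette, "Cassette"))
  if (is.null(chrom)) chrom <- cassette@id
  chrom <- gsub("[[:space:]]", "_", chrom)
  runs <- .maskRuns(cassette@homologyMask)
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = runs$start, end = runs$end),
    name = paste0("hom_", seq_len(nrow(runs))))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Import a homology mask from BED
#'
#' @param path `.bed` path written by [writeMaskBed()] (or any BED whose
#'   features mark homologous runs on one sequence).
#' @param length integer mask length in bp.
#' @return Logical mask of the given length, `TRUE` inside features.
#' @export
readMaskBed <- function(path, length) {
  gr <- rtracklayer::import(path, format = "bed")
  mask <- logical(length)
  if (base::length(gr)) {
    for (i in seq_along(gr)) {
      mask[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    }
  }
  mask
}

#' Write a cassette as a two-record FASTA
#'
#' Reference and test copies, wrapped at 70 columns. The homology mask needs
#' no separate serialization: it is recoverable as position-wise equality
#' (see [Cassette()]).
#'
#' @param cassette a [Cassette-class].
#' @param path output `.fasta` path.
#' @return Invisibly, `path`.
#' @export
writeCassetteFasta <- function(cassette, path) {
  stopifnot(is(cassette, "Cassette"))
  set <- Biostrings::DNAStringSet(c(as.character(cassette@referenceCopy),
                                    as.character(cassette@testCopy)))
  names(set) <- paste0(gsub("[[:space:]]", "_", cassette@id),
                       c("_ref", "_test"))
  Biostrings::writeXStringSet(set, filepath = path, width = 70)
  invisible(path)
}

#' Read a cassette from a two-record FASTA
#'
#' @param path FASTA with the reference copy first and the test copy second.
#' @param id cassette label (default from the first record name).
#' @return A [Cassette-class].
#' @export
readCassetteFasta <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 2) {
    stop("expected exactly 2 sequences (reference, test), found ",
         length(set), call. = FALSE)
  }
  if (is.null(id)) id <- sub("_ref$", "", names(set)[1])
  Cassette(as.character(set[[1]]), as.character(set[[2]]), id = id)
}

#' Read or write a pattern/composition configuration
#'
#' Plain YAML configuration with keys `X`, `Y`, `Z`, `L`, `end_policy`,
#' `extend_by`, `block_len`, `block_side`, `junction_insert_len`,
#' `interruption` (`[start, len]` or absent) and `seed`.
#'
#' @param path config file path.
#' @return For `readPatternConfig`, a list with elements `pattern`
#'   ([HomologyPattern-class]), `blockLen`, `blockSide`,
#'   `junctionInsertLen`, `interruption` and `seed`.
#' @export
readPatternConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  # a bare (unquoted) Y key is a YAML 1.1 boolean; accept it anyway
  if (is.null(cfg$Y) && !is.null(cfg[["TRUE"]])) cfg$Y <- cfg[["TRUE"]]
  for (key in c("X", "Y", "Z", "L")) {
    if (is.null(cfg[[key]])) stop("config is missing key '", key, "'",
                                  call. = FALSE)
  }
  pattern <- HomologyPattern(
    cfg$X, cfg$Y, cfg$Z, cfg$L,
    endPolicy = if (is.null(cfg$end_policy)) "truncate" else cfg$end_policy,
    extendBy = if (is.null(cfg$extend_by)) 0L else cfg$extend_by)
  list(pattern = pattern,
       blockLen = if (is.null(cfg$block_len)) 0L else as.integer(cfg$block_len),
       blockSide = if (is.null(cfg$block_side)) "none" else cfg$block_side,
       junctionInsertLen = if (is.null(cfg$junction_insert_len)) 0L
                           else as.integer(cfg$junction_insert_len),
       interruption = if (is.null(cfg$interruption)) NULL
                      else as.integer(cfg$interruption),
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' @rdname readPatternConfig
#' @param config list as returned by `readPatternConfig` (a
#'   [HomologyPattern-class] alone is also accepted).
#' @export
writePatternConfig <- function(config, path) {
  if (is(config, "HomologyPattern")) config <- list(pattern = config)
  p <- config$pattern
  stopifnot(is(p, "HomologyPattern"))
  out <- list(X = p@unitLen, Y = p@spacerLen, Z = p@seqPos, L = p@regionLen,
              end_policy = p@endPolicy, extend_by = p@extendBy)
  for (nm in c("blockLen", "blockSide", "junctionInsertLen", "seed")) {
    if (!is.null(config[[nm]])) {
      key <- c(blockLen = "block_len", blockSide = "block_side",
               junctionInsertLen = "junction_insert_len", seed = "seed")[nm]
      out[[key]] <- config[[nm]]
    }
  }
  if (!is.null(config$interruption)) out$interruption <- config$interruption
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write per-spore call and per-site profile tables
#'
#' `writeCallTable` writes one row per spore (`spore_id`, `n_CT`, `n_GA`,
#' `n_other`); `writeProfileTable` writes one row per position (`position`,
#' `count`, `percent`), both tab-separated with 1-based coordinates.
#'
#' @param calls list of [MutationCallSet-class].
#' @param profile a [SiteProfile-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeCallTable <- function(calls, path) {
  df <- data.frame(
    spore_id = vapply(calls, sporeId, character(1)),
    n_CT = vapply(calls, nCT, integer(1)),
    n_GA = vapply(calls, nGA, integer(1)),
    n_other = vapply(calls, nOther, integer(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCallTable
#' @export
writeProfileTable <- function(profile, path) {
  stopifnot(is(profile, "SiteProfile"))
  df <- data.frame(position = seq_along(profile@siteCounts),
                   count = profile@siteCounts,
                   percent = sitePercent(profile))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Verify recorded against recomputed mutation counts
#'
#' Re-calls every spore of a contig table against its expected sequence and
#' compares the recomputed C/T and G/A totals with the recorded CSV fields.
#'
#' @param records data.frame from [readS3Csv()].
#' @param expected named list (or single sequence) mapping RepeatID to the
#'   expected cassette sequence; spores are routed by the RepeatID parsed
#'   from their id.
#' @param mode passed to [callMutations()].
#' @return data.frame with recorded and recomputed counts and a logical
#'   `verified` column.
#' @export
verifyRecordedCounts <- function(records, expected,
                                 mode = c("positional", "gapped")) {
  mode <- match.arg(mode)
  ids <- parseSporeId(records$id)
  if (is.character(expected) && is.null(names(expected)) &&
      length(expected) == 1) {
    expected <- stats::setNames(rep(list(expected),
                                    length(unique(ids$repeatId))),
                                unique(ids$repeatId))
  }
  ct <- ga <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    exp <- expected[[ids$repeatId[i]]]
    if (is.null(exp)) {
      stop("no expected sequence for construct '", ids$repeatId[i], "'",
           call. = FALSE)
    }
    cs <- callMutations(exp, records$seq[i], mode = mode,
                        sporeId = records$id[i])
    ct[i] <- nCT(cs); ga[i] <- nGA(cs)
  }
  out <- data.frame(id = records$id,
                    n_CT_recorded = records$n_CT_recorded,
                    n_GA_recorded = records$n_GA_recorded,
                    n_CT_recomputed = ct, n_GA_recomputed = ga,
                    stringsAsFactors = FALSE)
  out$verified <- out$n_CT_recorded == out$n_CT_recomputed &
    out$n_GA_recorded == out$n_GA_recomputed
  if (!all(out$verified)) {
    message(sum(!out$verified),
            " spore(s) disagree between recorded and recomputed counts")
  }
  out
}
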