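#' Read a predicted proteome from FASTA
#'
#' Reads one predicted-proteome FASTA (one genome assembly) into an
#' \code{AAStringSet}. Sequences are upper-cased on read (lowercase input is
#' accepted with a warning); \code{X} and \code{*} are tolerated here and
#' removed later by \code{\link{removeInvalid}}. Provenance is attached as
#' metadata columns: \code{genome_id} defaults to the file-name stem when not
#' supplied.
#'
#' @param path FASTA file path.
#' @param genomeId Genome/assembly identifier; default: file-name stem.
#' @param species Optional species label.
#' @return \code{AAStringSet} with names = protein ids and mcols
#'   \code{genome_id}, \code{species}. Input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKL"), tf)
#' readProteome(tf, genomeId = "g1")
#' @export
readProteome <- function(path, genomeId = NULL, species = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  aa <- Biostrings::readBStringSet(path)
  if (length(aa) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- as.character(aa)
  if (any(!nzchar(seqs))) {
    bad <- names(aa)[!nzchar(seqs)][1]
    stop("empty sequence for record '", bad, "' in ", path, call. = FALSE)
  }
  if (any(grepl("[a-z]", seqs))) {
    warning("lowercase residues found in ", path, "; upper-casing")
    seqs <- toupper(seqs)
  }
  ok <- grepl("^[A-Z*]+$", seqs)
  if (!all(ok))
    stop("malformed sequence for record '", names(aa)[!ok][1], "'",
         call. = FALSE)
  # keep only the first whitespace-delimited token of the header as the id
  ids <- sub("\\s.*$", "", names(aa))
  if (any(!nzchar(ids))) stop("malformed (empty) FASTA header", call. = FALSE)
  if (is.null(genomeId))
    genomeId <- sub("\\.(fa|fasta|faa)(\\.gz)?$", "",
                    basename(path), ignore.case = TRUE)
  if (anyDuplicated(ids))
    stop("duplicate protein ids within genome '", genomeId, "': ",
         ids[duplicated(ids)][1], call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    genome_id = rep(genomeId, length(out)),
    species = rep(species, length(out)))
  out
}

#' Combine per-genome proteomes into one set
#'
#' @param ... \code{AAStringSet} objects from \code{\link{readProteome}}.
#' @return A single \code{AAStringSet}; mcols are concatenated.
#' @examples
#' a <- Biostrings::AAStringSet(c(p1 = "MKL")); S4Vectors::mcols(a) <-
#'   S4Vectors::DataFrame(genome_id = "g1", species = NA)
#' combineProteomes(a, a)
#' @export
combineProteomes <- function(...) {
  parts <- list(...)
  out <- do.call(c, parts)
  S4Vectors::mcols(out) <- do.call(rbind, lapply(parts, S4Vectors::mcols))
  out
}

#' Write sequences to FASTA
#'
#' @param x Named character vector or \code{AAStringSet}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @examples
#' writeFasta(c(p1 = "MKL"), tempfile(fileext = ".fasta"))
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) x <- Biostrings::AAStringSet(x)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.parsePropeptideSites <- function(txt) {
  lapply(strsplit(ifelse(is.na(txt) | txt == "", NA_character_, txt), ";"),
         function(v) if (all(is.na(v))) integer() else sort(as.integer(v)))
}

#' Read cleavage annotations (generic TSV dialect)
#'
#' The generic dialect has columns \code{protein_id}, \code{signal_end}
#' (1-based position of the last signal-peptide residue) and
#' \code{propeptide_sites} (";"-separated 1-based positions, each the last
#' residue before a cleavage point; may be empty). Rows without a positive
#' signal-peptide call (empty \code{signal_end}) are dropped and counted.
#'
#' @param path TSV path.
#' @param proteins Optional \code{AAStringSet}; when given, positions are
#'   validated against sequence lengths.
#' @return data.frame with \code{protein_id}, \code{signal_end} (integer)
#'   and list-column \code{propeptide_sites}.
#' @examples
#' tf <- tempfile(); writeLines(
#'   c("protein_id\tsignal_end\tpropeptide_sites", "p1\t20\t35;50"), tf)
#' readCleavageTsv(tf)
#' @export
readCleavageTsv <- function(path, proteins = NULL) {
  df <- utils::read.delim(path, colClasses = "character")
  need <- c("protein_id", "signal_end", "propeptide_sites")
  if (!all(need %in% names(df)))
    stop("not a generic cleavage TSV (need columns ",
         paste(need, collapse = ", "), "): ", path, call. = FALSE)
  keep <- nzchar(df$signal_end) & !is.na(df$signal_end)
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " row(s) without a signal-peptide call dropped")
  df <- df[keep, , drop = FALSE]
  ann <- data.frame(protein_id = df$protein_id,
                    signal_end = as.integer(df$signal_end),
                    stringsAsFactors = FALSE)
  ann$propeptide_sites <- .parsePropeptideSites(df$propeptide_sites)
  .validateAnnotations(ann, proteins)
}

.validateAnnotations <- function(ann, proteins = NULL) {
  bad <- vapply(seq_len(nrow(ann)), function(i) {
    s <- ann$signal_end[i]; p <- ann$propeptide_sites[[i]]
    s < 1L || (length(p) && (any(p <= s) || is.unsorted(p, strictly = TRUE)))
  }, logical(1))
  if (any(bad))
    stop("invalid cleavage annotation for protein_id ",
         ann$protein_id[bad][1],
         " (signal_end must precede all strictly increasing propeptide sites)",
         call. = FALSE)
  if (!is.null(proteins)) {
    len <- stats::setNames(Biostrings::width(proteins), names(proteins))
    hit <- ann$protein_id %in% names(len)
    over <- vapply(which(hit), function(i) {
      L <- len[[ann$protein_id[i]]]
      ann$signal_end[i] > L || any(ann$propeptide_sites[[i]] > L)
    }, logical(1))
    if (any(over))
      stop("cleavage position out of range for protein_id ",
           ann$protein_id[hit][over][1], call. = FALSE)
  }
  ann
}

#' Read SignalP 4.1 "short" output
#'
#' Parses the whitespace-delimited short format (comment lines start with
#' \code{#}; columns include \code{name}, \code{Ymax pos}, \code{D} and the
#' \code{?} column holding Y/N). Only proteins with a positive call
#' (\code{?} == "Y") are returned; \code{signal_end} is the cleavage-site
#' column minus one (SignalP reports the first residue of the mature chain).
#'
#' @param path SignalP 4.1 short-format file.
#' @return data.frame with \code{protein_id}, \code{signal_end}.
#' @examples
#' tf <- tempfile()
#' writeLines(c("# SignalP-4.1 euk predictions",
#'  "# name Cmax pos Ymax pos Smax pos Smean D ? Dmaxcut Networks-used",
#'  "p1 0.8 21 0.8 21 0.9 5 0.8 0.82 Y 0.450 SignalP-noTM",
#'  "p2 0.1 10 0.1 10 0.1 2 0.1 0.10 N 0.450 SignalP-noTM"), tf)
#' readSignalp(tf)
#' @export
readSignalp <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (!length(ln))
    return(data.frame(protein_id = character(), signal_end = integer()))
  parts <- strsplit(trimws(ln), "\\s+")
  ncols <- lengths(parts)
  if (any(ncols < 10L))
    stop("not SignalP 4.1 short format: ", path, call. = FALSE)
  id   <- vapply(parts, `[`, character(1), 1L)
  ymax <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 5L)))
  call <- vapply(parts, `[`, character(1), 10L)
  if (anyNA(ymax) || !all(call %in% c("Y", "N")))
    stop("not SignalP 4.1 short format: ", path, call. = FALSE)
  pos <- call == "Y"
  data.frame(protein_id = id[pos], signal_end = ymax[pos] - 1L,
             stringsAsFactors = FALSE)
}

#' Read ProP 1.0 output
#'
#' Parses the text output of ProP 1.0, collecting predicted propeptide
#' cleavage sites (lines of the form
#' \code{"  <pos> <res> .. <score>  *ProP*"} within each sequence block
#' introduced by \code{"Name: <id>"}). Positions are the residue
#' N-terminal to the cleavage point.
#'
#' @param path ProP output file.
#' @return data.frame with \code{protein_id} and list-column
#'   \code{propeptide_sites}.
#' @export
readProp <- function(path) {
  ln <- readLines(path)
  cur <- NA_character_
  ids <- character(); sites <- list()
  for (l in ln) {
    m <- regmatches(l, regexec("^\\s*Name:\\s+(\\S+)", l))[[1]]
    if (length(m)) {
      cur <- m[2]
      if (!cur %in% ids) { ids <- c(ids, cur); sites[[cur]] <- integer() }
      next
    }
    if (!is.na(cur) && grepl("\\*ProP\\*", l)) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      pos <- suppressWarnings(as.integer(tok[1]))
      if (is.na(pos)) stop("unparseable ProP site line: ", l, call. = FALSE)
      sites[[cur]] <- c(sites[[cur]], pos)
    }
  }
  if (!length(ids) && length(ln))
    stop("not ProP 1.0 output (no 'Name:' blocks): ", path, call. = FALSE)
  data.frame(protein_id = ids,
             propeptide_sites = I(lapply(sites[ids], sort)),
             stringsAsFactors = FALSE)
}

#' Merge SignalP and ProP outputs into cleavage annotations
#'
#' Only proteins with a positive SignalP call appear; ProP sites located at
#' or before the signal end are discarded.
#'
#' @param signalp data.frame from \code{\link{readSignalp}} (or a path).
#' @param prop Optional data.frame from \code{\link{readProp}} (or a path).
#' @param proteins Optional \code{AAStringSet} for position validation.
#' @return data.frame as in \code{\link{readCleavageTsv}}.
#' @export
cleavageAnnotations <- function(signalp, prop = NULL, proteins = NULL) {
  if (is.character(signalp)) signalp <- readSignalp(signalp)
  if (is.character(prop)) prop <- readProp(prop)
  ann <- data.frame(protein_id = signalp$protein_id,
                    signal_end = as.integer(signalp$signal_end),
                    stringsAsFactors = FALSE)
  ann$propeptide_sites <- replicate(nrow(ann), integer(), simplify = FALSE)
  if (!is.null(prop)) {
    idx <- match(ann$protein_id, prop$protein_id)
    for (i in which(!is.na(idx))) {
      p <- prop$propeptide_sites[[idx[i]]]
      ann$propeptide_sites[[i]] <- p[p > ann$signal_end[i]]
    }
  }
  .validateAnnotations(ann, proteins)
}

#' Write result records as TSV or JSON
#'
#' Columns are written in a deterministic order (as given in the input
#' data.frame); list-columns are flattened with ";" for TSV. JSON output is
#' an array of row objects and round-trips through
#' \code{\link{readResults}}.
#'
#' @param records data.frame of peptide/group records.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return Invisibly, \code{path}.
#' @examples
#' writeResults(data.frame(id = "p1", n = 2L), tempfile(), "tsv")
#' @export
writeResults <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  if (format == "tsv") {
    flat <- records
    for (j in seq_along(flat))
      if (is.list(flat[[j]]))
        flat[[j]] <- vapply(flat[[j]], paste, character(1), collapse = ";")
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read result records written by writeResults
#'
#' @param path File path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return data.frame.
#' @export
readResults <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") utils::read.delim(path)
  else jsonlite::fromJSON(path)
}
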