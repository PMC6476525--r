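#' Read transcripts from a FASTA file plus a CDS coordinate table
#'
#' The coordinate table is tab-delimited with header
#' `id, gene, species, cds_start, cds_end`; every FASTA record id must have
#' exactly one row. Records that fail validation are reported, never silently
#' dropped: in strict mode (default) the first problem is fatal; otherwise
#' valid records are returned and the problems are attached as the
#' `"problems"` attribute (a data frame with columns `id`, `problem`).
#'
#' @param fasta path to a FASTA file of mRNA-space sequences.
#' @param cds_table path to the tab-delimited coordinate table.
#' @param validate_cds passed to [transcript()].
#' @param strict if `TRUE`, any invalid record is a fatal error naming it.
#' @return a named list of [transcript()] objects, with attribute
#'   `"problems"`.
#' @export
read_transcripts <- function(fasta, cds_table, validate_cds = FALSE,
                             strict = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  tab <- utils::read.delim(cds_table, stringsAsFactors = FALSE)
  need <- c("id", "gene", "species", "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stop("CDS table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$id))
    stop("CDS table has duplicated ids: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))

  out <- list()
  problems <- data.frame(id = character(), problem = character())
  fail <- function(id, msg) {
    if (strict) stop("record '", id, "': ", msg)
    problems[nrow(problems) + 1L, ] <<- list(id, msg)
  }
  for (i in seq_along(ids)) {
    id <- ids[i]
    row <- tab[tab$id == id, , drop = FALSE]
    if (nrow(row) == 0L) {
      fail(id, "no row in the CDS coordinate table")
      next
    }
    tx <- tryCatch(
      transcript(id, as.character(seqs[[i]]), row$cds_start, row$cds_end,
                 gene = row$gene, species = row$species,
                 validate_cds = validate_cds),
      error = function(e) conditionMessage(e))
    if (is.character(tx)) fail(id, tx) else out[[id]] <- tx
  }
  attr(out, "problems") <- problems
  out
}

#' Write transcripts back to FASTA plus a CDS coordinate table
#'
#' The inverse of [read_transcripts()]: re-reading the two files yields
#' identical transcript objects.
#'
#' @param transcripts a list of [transcript()] objects.
#' @param fasta,cds_table output paths.
#' @return invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta, cds_table) {
  stopifnot(length(transcripts) > 0L)
  seqs <- Biostrings::DNAStringSet(vapply(transcripts, `[[`, "", "seq"))
  names(seqs) <- vapply(transcripts, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta)
  tab <- data.frame(
    id = vapply(transcripts, `[[`, "", "id"),
    gene = vapply(transcripts, `[[`, "", "gene"),
    species = vapply(transcripts, `[[`, "", "species"),
    cds_start = vapply(transcripts, `[[`, 0L, "cds_start"),
    cds_end = vapply(transcripts, `[[`, 0L, "cds_end"))
  utils::write.table(tab, cds_table, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, cds_table = cds_table))
}

#' Read transcripts from a GenBank-style flat file
#'
#' A deliberately small parser for single-interval CDS features in mRNA-space
#' records: it reads `LOCUS` (record name), the first `CDS a..b` feature line,
#' optional `/gene=` and `/organism=` qualifiers, and the `ORIGIN` sequence
#' block. Joined (multi-interval) CDS locations are out of scope and fatal.
#'
#' @param path path to a GenBank flat file (one or more records separated by
#'   `//`).
#' @param validate_cds passed to [transcript()].
#' @return a named list of [transcript()] objects.
#' @export
read_genbank <- function(path, validate_cds = FALSE) {
  lines <- readLines(path)
  rec_end <- grep("^//\\s*$", lines)
  if (length(rec_end) == 0L) stop("no GenBank record terminator '//' found")
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)
  out <- list()
  for (k in seq_along(rec_end)) {
    rec <- lines[rec_start[k]:rec_end[k]]
    locus <- grep("^LOCUS", rec, value = TRUE)
    if (length(locus) == 0L) next
    id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
    ver <- grep("^VERSION", rec, value = TRUE)
    if (length(ver) > 0L) {
      v <- strsplit(trimws(sub("^VERSION", "", ver[1])), "\\s+")[[1]][1]
      if (nzchar(v) && !is.na(v)) id <- v
    }
    cds_line <- grep("^\\s{5}CDS\\s", rec, value = TRUE)
    if (length(cds_line) == 0L)
      stop("GenBank record '", id, "': no CDS feature")
    loc <- trimws(sub("^\\s{5}CDS\\s+", "", cds_line[1]))
    if (grepl("join|complement", loc))
      stop("GenBank record '", id, "': only single-interval CDS on the ",
           "sense strand is supported (got '", loc, "')")
    m <- regmatches(loc, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc))[[1]]
    if (length(m) != 3L)
      stop("GenBank record '", id, "': unparseable CDS location '", loc, "'")
    qualifier <- function(name) {
      hit <- grep(paste0("/", name, "="), rec, value = TRUE)
      if (length(hit) == 0L) return("")
      m <- regmatches(hit[1],
                      regexec(paste0('/', name, '="([^"]*)"'), hit[1]))[[1]]
      if (length(m) == 2L) m[2] else ""
    }
    gene <- qualifier("gene")
    organism <- qualifier("organism")
    ori <- grep("^ORIGIN", rec)
    if (length(ori) == 0L)
      stop("GenBank record '", id, "': no ORIGIN sequence block")
    seq_lines <- rec[(ori[1] + 1L):(length(rec) - 1L)]
    seq <- gsub("[^A-Za-z]", "", paste(seq_lines, collapse = ""))
    out[[id]] <- transcript(id, seq, as.integer(m[2]), as.integer(m[3]),
                            gene = gene, species = organism,
                            validate_cds = validate_cds)
  }
  out
}

#' Tabulate UTR regions for a set of transcripts
#'
#' @param transcripts a list of [transcript()] objects.
#' @return a data frame with one row per present region
#'   (`id`, `kind`, `start`, `end`, `length`).
#' @export
region_report <- function(transcripts) {
  rows <- list()
  for (t in transcripts) {
    u <- extract_utrs(t)
    for (r in list(u$utr5,
                   region(t$id, "cds", t$cds_start, t$cds_end,
                          substr(t$seq, t$cds_start, t$cds_end)),
                   u$utr3)) {
      if (is.null(r)) next
      rows[[length(rows) + 1L]] <- data.frame(
        id = t$id, kind = r$kind, start = r$start, end = r$end,
        length = nchar(r$seq))
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Fetch a RefSeq mRNA record from NCBI as a transcript
#'
#' Downloads the GenBank flat record for an accession via NCBI efetch and
#' parses it with [read_genbank()]. Requires network access; intended for
#' checking classifications and primer amplicons against real annotated
#' records rather than for routine offline use.
#'
#' @param accession a RefSeq nucleotide accession, e.g. `"NM_000584"`.
#' @param timeout seconds before the download attempt is abandoned.
#' @return a [transcript()] object.
#' @export
fetch_refseq <- function(accession, timeout = 30) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&id=", accession, "&rettype=gb&retmode=text")
  dest <- tempfile(fileext = ".gb")
  on.exit(unlink(dest), add = TRUE)
  old <- options(timeout = timeout)
  on.exit(options(old), add = TRUE)
  status <- tryCatch(
    utils::download.file(url, dest, quiet = TRUE, mode = "wb"),
    error = function(e) stop("could not fetch '", accession, "' from NCBI: ",
                             conditionMessage(e)))
  if (status != 0L || !file.exists(dest) || file.size(dest) == 0L)
    stop("could not fetch '", accession, "' from NCBI")
  recs <- read_genbank(dest)
  if (length(recs) == 0L)
    stop("no parseable GenBank record returned for '", accession, "'")
  recs[[1]]
}
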