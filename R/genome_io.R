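#' Load a genome assembly from FASTA
#'
#' Reads a multi-FASTA nucleotide file into a named, uppercased
#' \link[Biostrings]{DNAStringSet}. Contig identifiers are taken as the first
#' whitespace-delimited token of each header and must be unique. Ambiguity
#' codes other than \code{N} are rejected: downstream ORF and context scoring
#' treats \code{N} as an unknown base but has no defined semantics for partial
#' ambiguity codes.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A \code{DNAStringSet}, one element per contig, uppercase.
#' @export
load_assembly <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    dup <- unique(names(seqs)[duplicated(names(seqs))])
    stop("duplicate contig id(s) in ", fasta_path, ": ",
         paste(dup, collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- vapply(as.character(seqs),
                function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) {
    stop("contig(s) contain ambiguity codes other than N: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  seqs
}

#' Assemble spliced transcript models from a GFF3 annotation
#'
#' Joins \code{exon} and \code{CDS} features by their \code{Parent} mRNA,
#' splices the exonic genomic sequence, orients it to mRNA sense
#' (reverse-complementing minus-strand transcripts), and splits it into
#' 5'UTR, CDS and 3'UTR at the annotated CDS boundaries. Each mRNA record
#' yields one model; transcripts sharing a gene are treated independently.
#'
#' mRNAs without any CDS feature are skipped with a warning. A CDS segment
#' falling outside its transcript's exons is an error for that transcript
#' only; the remaining transcripts are still returned.
#'
#' @param assembly A \code{DNAStringSet} from \code{\link{load_assembly}}.
#' @param gff3_path Path to a GFF3 file with gene/mRNA/exon/CDS features and
#'   ID/Parent attributes.
#' @return A data frame of class \code{transcript_models} with one row per
#'   transcript: \code{transcript_id}, \code{gene_id}, \code{contig},
#'   \code{strand}, \code{utr5}, \code{cds}, \code{utr3} (mRNA-sense
#'   strings) and list-columns \code{exon_starts}, \code{exon_ends},
#'   \code{cds_starts}, \code{cds_ends} (1-based genomic, ascending).
#' @export
assemble_transcripts <- function(assembly, gff3_path) {
  gff <- rtracklayer::import(gff3_path, format = "gff3")
  ftype <- as.character(gff$type)
  parent_of <- function(plist) {
    vapply(plist, function(pi) {
      if (length(pi) == 0L) NA_character_ else as.character(pi[1L])
    }, character(1))
  }
  # flatten to plain vectors once; per-transcript work is then base R
  feat <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gff)),
    start = BiocGenerics::start(gff), end = BiocGenerics::end(gff),
    strand = as.character(BiocGenerics::strand(gff)),
    type = ftype, id = as.character(gff$ID),
    parent = parent_of(gff$Parent), stringsAsFactors = FALSE)

  is_mrna <- feat$type %in% c("mRNA", "transcript")
  if (!any(is_mrna)) stop("no mRNA features in ", gff3_path)
  mrna <- feat[is_mrna, , drop = FALSE]
  exon_by_parent <- split(which(feat$type == "exon"),
                          feat$parent[feat$type == "exon"])
  cds_by_parent <- split(which(feat$type == "CDS"),
                         feat$parent[feat$type == "CDS"])

  missing_contig <- setdiff(unique(mrna$contig), names(assembly))
  if (length(missing_contig) > 0L) {
    stop("annotation references contig(s) absent from assembly: ",
         paste(missing_contig, collapse = ", "))
  }
  contig_str <- stats::setNames(as.character(assembly), names(assembly))

  out <- vector("list", nrow(mrna))
  kept <- logical(nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    tid <- mrna$id[i]
    ex <- feat[exon_by_parent[[tid]], , drop = FALSE]
    cd <- feat[cds_by_parent[[tid]], , drop = FALSE]
    if (nrow(cd) == 0L) {
      warning("mRNA '", tid, "' has no CDS feature; skipped", call. = FALSE)
      next
    }
    if (nrow(ex) == 0L) ex <- cd  # CDS-only annotation: exons implied
    model <- tryCatch(
      splice_model(contig_str[[mrna$contig[i]]], tid, mrna$parent[i],
                   mrna$contig[i], mrna$strand[i],
                   sort(ex$start), ex$end[order(ex$start)],
                   sort(cd$start), cd$end[order(cd$start)]),
      error = function(e) {
        warning("transcript '", tid, "' dropped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      }
    )
    if (!is.null(model)) {
      out[[i]] <- model
      kept[i] <- TRUE
    }
  }
  out <- out[kept]
  if (length(out) == 0L) stop("no usable transcript models in ", gff3_path)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

## Splice one transcript and split at CDS borders (internal).
splice_model <- function(contig_seq, tid, gid, contig, strand,
                         exs, exe, cds, cde) {
  # every CDS base must lie within some exon
  for (k in seq_along(cds)) {
    hit <- which(cds[k] >= exs & cde[k] <= exe)
    if (length(hit) == 0L) stop("CDS outside exons")
  }

  pieces <- substring(contig_seq, exs, exe)
  spliced <- paste(pieces, collapse = "")

  # map genomic position -> 0-based transcript coordinate (plus-strand order)
  ex_w <- exe - exs + 1L
  offs <- cumsum(c(0L, ex_w[-length(ex_w)]))
  g2t <- function(gpos) {
    k <- which(gpos >= exs & gpos <= exe)
    if (length(k) != 1L) stop("position not exonic")
    offs[k] + (gpos - exs[k])
  }
  tlen <- nchar(spliced)
  first_cds <- g2t(min(cds))          # 0-based, plus orientation
  last_cds  <- g2t(max(cde))
  if (strand == "-") {
    seq_mrna <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(spliced)))
    cds_start <- tlen - 1L - last_cds  # 0-based in mRNA sense
    cds_end   <- tlen - 1L - first_cds
  } else {
    seq_mrna <- spliced
    cds_start <- first_cds
    cds_end   <- last_cds
  }
  data.frame(
    transcript_id = tid, gene_id = gid, contig = contig, strand = strand,
    utr5 = substr(seq_mrna, 1L, cds_start),
    cds  = substr(seq_mrna, cds_start + 1L, cds_end + 1L),
    utr3 = substr(seq_mrna, cds_end + 2L, tlen),
    exon_starts = I(list(exs)), exon_ends = I(list(exe)),
    cds_starts = I(list(cds)), cds_ends = I(list(cde)),
    stringsAsFactors = FALSE
  )
}

#' Translate a nucleotide sequence to peptide
#'
#' Standard genetic code; translation stops at the first stop codon and a
#' trailing partial codon is ignored. Codons containing \code{N} translate
#' to \code{X}.
#'
#' @param cds_seq A nucleotide string of length >= 3.
#' @return Peptide string (no stop character).
#' @export
translate_cds <- function(cds_seq) {
  if (nchar(cds_seq) < 3L) stop("sequence shorter than one codon")
  n_cod <- nchar(cds_seq) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- substring(cds_seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"                  # codons containing N
  pep <- paste(aa, collapse = "")
  sub("\\*.*$", "", pep)
}

#' Write per-transcript region FASTA
#'
#' Emits the spliced 5'UTR, CDS and 3'UTR of each transcript as separate
#' FASTA records with ids suffixed \code{.utr5}/\code{.cds}/\code{.utr3};
#' empty regions are omitted.
#'
#' @param models A \code{transcript_models} data frame.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_region_fasta <- function(models, path) {
  ids <- c(); seqs <- c()
  for (region in c("utr5", "cds", "utr3")) {
    keep <- nchar(models[[region]]) > 0L
    ids <- c(ids, paste0(models$transcript_id[keep], ".", region))
    seqs <- c(seqs, models[[region]][keep])
  }
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
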