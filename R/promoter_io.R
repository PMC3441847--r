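#' Construct a PromoterSet
#'
#' A labeled collection of fixed-length promoter sequences tied to gene IDs.
#' Sequences are stored uppercase over the alphabet A, C, G, T, N and always
#' read 5'->3' in transcript orientation.
#'
#' @param seqs `DNAStringSet` (or character vector) named by gene_id.
#' @param info data.frame with columns gene_id, chrom, strand, start, end,
#'   truncated (genomic coordinates, 0-based half-open); built from names if
#'   omitted.
#' @param label set label, e.g. a subtype name.
#' @return object of class `PromoterSet` with fields `seqs`, `info`, `label`.
#' @export
promoter_set <- function(seqs, info = NULL, label = "promoters") {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  nm <- names(seqs)
  if (is.null(nm) || anyDuplicated(nm))
    stop("promoter sequences must carry unique gene_id names")
  if (is.null(info)) {
    info <- data.frame(gene_id = nm, chrom = NA_character_,
                       strand = "+", start = 0L,
                       end = Biostrings::width(seqs), truncated = FALSE,
                       stringsAsFactors = FALSE)
  }
  stopifnot(identical(info$gene_id, nm))
  structure(list(seqs = seqs, info = info, label = label),
            class = "PromoterSet")
}

#' @export
print.PromoterSet <- function(x, ...) {
  cat("<PromoterSet> '", x$label, "': ", length(x$seqs), " promoters, ",
      sum(Biostrings::width(x$seqs)), " bp total\n", sep = "")
  invisible(x)
}

#' @export
length.PromoterSet <- function(x) length(x$seqs)

#' Extract promoter windows around TSSs from a genome
#'
#' Returns the window from `upstream` bp upstream to `downstream` bp
#' downstream of each TSS (default -500..+100, 600 bp), with the TSS at
#' offset `upstream` (0-based) of the returned sequence. For a plus-strand
#' TSS at genomic position t the half-open window is `[t-upstream,
#' t+downstream)`; for a minus strand TSS the mirrored window
#' `[t-downstream+1, t+upstream+1)` is reverse-complemented so the sequence
#' reads 5'->3'. Windows truncated at contig edges are padded with N to the
#' fixed length and flagged.
#'
#' @param genome FASTA path or named `DNAStringSet`.
#' @param tss BED6 path (or `GRanges`) of one TSS record per gene; the name
#'   field is the gene_id. For a record the TSS is taken as the BED start on
#'   "+" and the BED end minus one on "-".
#' @param upstream,downstream window extents in bp.
#' @param label label for the resulting set.
#' @return a [promoter_set()].
#' @export
extract_promoters <- function(genome, tss, upstream = 500L,
                              downstream = 100L, label = "promoters") {
  stopifnot(upstream >= 0, downstream >= 1)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- if (is.character(tss)) rtracklayer::import(tss, format = "BED")
        else tss
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*"))
    stop("TSS records without strand: ",
         paste(head(which(strand == "*")), collapse = ", "))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(chrom), names(genome))
  if (length(bad))
    stop("chromosomes not in genome FASTA: ", paste(bad, collapse = ", "))
  gene_id <- gr$name
  if (is.null(gene_id) || anyNA(gene_id))
    stop("TSS BED records must carry gene ids in the name field")
  # 0-based TSS coordinate
  t0 <- ifelse(strand == "+",
               GenomicRanges::start(gr) - 1L,
               GenomicRanges::end(gr) - 1L)
  win_len <- upstream + downstream
  w_start <- ifelse(strand == "+", t0 - upstream, t0 - downstream + 1L)
  w_end <- w_start + win_len
  out <- character(length(gr))
  truncated <- logical(length(gr))
  for (i in seq_along(gr)) {
    clen <- length(genome[[chrom[i]]])
    s <- max(w_start[i], 0L)
    e <- min(w_end[i], clen)
    if (e <= s) {
      core <- ""
    } else {
      core <- as.character(Biostrings::subseq(genome[[chrom[i]]],
                                              start = s + 1L, end = e))
    }
    left <- s - w_start[i]
    right <- w_end[i] - max(e, s)
    truncated[i] <- left > 0L || right > 0L
    seqc <- paste0(strtrim(strrep("N", max(left, 0L)), max(left, 0L)), core,
                   strtrim(strrep("N", max(right, 0L)), max(right, 0L)))
    if (strand[i] == "-")
      seqc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(seqc)))
    out[i] <- toupper(seqc)
  }
  seqs <- Biostrings::DNAStringSet(setNames(out, gene_id))
  info <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                     start = w_start, end = w_end, truncated = truncated,
                     stringsAsFactors = FALSE)
  promoter_set(seqs, info, label)
}

#' Subset a PromoterSet to a gene list
#'
#' @param promoters a [promoter_set()].
#' @param gene_list character vector of gene_ids, or path to a one-column TSV.
#' @param label new set label.
#' @return a [promoter_set()] with the listed genes in list order; unresolved
#'   gene_ids are reported with their count.
#' @export
subset_by_genes <- function(promoters, gene_list, label) {
  stopifnot(inherits(promoters, "PromoterSet"))
  if (length(gene_list) == 1L && file.exists(gene_list)) {
    gene_list <- read_tsv(gene_list, header = FALSE)[[1]]
  }
  gene_list <- as.character(gene_list)
  if (!length(gene_list)) stop("empty gene list")
  gene_list <- unique(gene_list)
  found <- gene_list[gene_list %in% promoters$info$gene_id]
  missing <- setdiff(gene_list, found)
  if (!length(found))
    stop("no gene in the list resolves in promoter set '",
         promoters$label, "'")
  if (length(missing))
    warning(length(missing), " gene id(s) not found: ",
            paste(head(missing, 5L), collapse = ", "),
            if (length(missing) > 5L) ", ...")
  idx <- match(found, promoters$info$gene_id)
  promoter_set(promoters$seqs[idx], promoters$info[idx, , drop = FALSE],
               label)
}

#' Write a PromoterSet to FASTA
#'
#' Headers have the form `gene_id|chrom|strand|start-end`.
#' @param promoters a [promoter_set()].
#' @param path output FASTA path.
#' @export
write_promoters_fasta <- function(promoters, path) {
  hdr <- with(promoters$info,
              paste(gene_id, ifelse(is.na(chrom), ".", chrom), strand,
                    paste0(start, "-", end), sep = "|"))
  seqs <- promoters$seqs
  names(seqs) <- hdr
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}

#' Read a PromoterSet from FASTA
#'
#' Accepts headers written by [write_promoters_fasta()] or plain gene_id
#' headers.
#' @param path FASTA path.
#' @param label set label.
#' @return a [promoter_set()].
#' @export
read_promoters_fasta <- function(path, label = "promoters") {
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  gene_id <- vapply(parts, `[[`, "", 1L)
  info <- if (all(lengths(parts) >= 4L)) {
    coords <- strsplit(vapply(parts, `[[`, "", 4L), "-", fixed = TRUE)
    data.frame(gene_id = gene_id,
               chrom = vapply(parts, `[[`, "", 2L),
               strand = vapply(parts, `[[`, "", 3L),
               start = as.integer(vapply(coords, `[[`, "", 1L)),
               end = as.integer(vapply(coords, `[[`, "", 2L)),
               truncated = NA, stringsAsFactors = FALSE)
  } else NULL
  names(seqs) <- gene_id
  if (!is.null(info)) info$truncated <- grepl("N", as.character(seqs))
  promoter_set(seqs, info, label)
}
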