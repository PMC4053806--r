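#' Load sequences from a FASTA file as RNA
#'
#' Reads a (multi-)FASTA file, uppercases, converts T to U, and validates the
#' alphabet. Characters outside `{A,C,G,U,N}` are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of RNA sequences. Names are the first
#'   whitespace-delimited token of each header.
#' @export
load_fasta <- function(path) {
  xs <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(xs))
  seqs <- chartr("T", "U", seqs)
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    stop("sequence(s) with characters outside {A,C,G,U,N,T}: ",
         paste(head(names(xs)[bad], 3L), collapse = ", "))
  }
  names(seqs) <- sub("\\s.*$", "", names(xs))
  seqs
}

resolve_seqs <- function(fasta_source) {
  if (is.character(fasta_source) && length(fasta_source) == 1L &&
      is.null(names(fasta_source)) && file.exists(fasta_source)) {
    return(load_fasta(fasta_source))
  }
  if (is.character(fasta_source) && !is.null(names(fasta_source))) {
    return(chartr("T", "U", toupper(fasta_source)))
  }
  stop("'fasta_source' must be a FASTA path or a named character vector")
}

#' Load binding-site intervals
#'
#' Reads BED6 intervals, checks them against the reference sequences, and
#' applies the protocol-specific preprocessing: iCLIP sites (single
#' cross-link positions) are extended by 15 nucleotides upstream and
#' downstream (clipped to the sequence bounds) before any other processing;
#' intervals from other protocols are used unchanged.
#'
#' @param bed_source Path to a BED file, or a `GRanges` object.
#' @param fasta_source Path to a FASTA file, or a named character vector of
#'   sequences (used to validate intervals and clip extensions).
#' @param protocol One of `"HITS-CLIP"`, `"PAR-CLIP"`, `"iCLIP"`,
#'   `"generic"`.
#' @return A `GRanges` of binding sites (1-based, closed, per the R interval
#'   convention). Intervals extending beyond a sequence end are dropped with
#'   a warning; intervals on unknown sequences are an error.
#' @export
load_sites <- function(bed_source, fasta_source,
                       protocol = c("HITS-CLIP", "PAR-CLIP", "iCLIP", "generic")) {
  protocol <- match.arg(protocol)
  seqs <- resolve_seqs(fasta_source)
  gr <- if (methods::is(bed_source, "GRanges")) bed_source
        else rtracklayer::import(bed_source, format = "BED")
  lens <- nchar(seqs)
  sn <- as.character(GenomicRanges::seqnames(gr))
  unknown <- !(sn %in% names(seqs))
  if (any(unknown)) {
    stop("interval(s) on sequences absent from the FASTA: ",
         paste(unique(sn[unknown]), collapse = ", "))
  }
  beyond <- GenomicRanges::end(gr) > lens[sn] | GenomicRanges::start(gr) < 1L
  if (any(beyond)) {
    warning(sum(beyond), " interval(s) beyond sequence bounds dropped")
    gr <- gr[!beyond]
    sn <- sn[!beyond]
  }
  strand <- as.character(GenomicRanges::strand(gr))
  GenomicRanges::strand(gr)[strand == "*"] <- "+"
  if (protocol == "iCLIP" && length(gr)) {
    st <- pmax(1L, GenomicRanges::start(gr) - 15L)
    en <- pmin(lens[sn], GenomicRanges::end(gr) + 15L)
    GenomicRanges::ranges(gr) <- IRanges::IRanges(start = st, end = en)
  }
  if (is.null(gr$name) && length(gr)) {
    gr$name <- sprintf("site_%04d", seq_along(gr))
  }
  gr
}

#' Drop binding sites longer than a maximum length
#'
#' Binding sites of more than `max_len` nucleotides are excluded from
#' training sets; order is preserved and the filter is idempotent.
#'
#' @param sites A `GRanges` of binding sites.
#' @param max_len Maximum retained width in nucleotides. Default 75.
#' @return The filtered `GRanges`.
#' @export
filter_sites <- function(sites, max_len = 75L) {
  sites[GenomicRanges::width(sites) <= max_len]
}

#' Generate matched unbound (negative) sites
#'
#' Creates one unbound site per bound site by shuffling coordinates within
#' genes occupied by at least one binding site: each negative keeps the
#' length and strand of its source positive and is placed uniformly at
#' random (seeded) within the gene bounds, rejecting placements that overlap
#' any positive. Sites for which no non-overlapping placement is found after
#' `max_attempts` rejections are dropped with a warning.
#'
#' @param positives `GRanges` of bound sites.
#' @param gene_bounds Data frame with columns `seqname`, `start`, `end`
#'   (1-based, closed) delimiting each occupied gene, or a named numeric
#'   vector of sequence lengths (bounds are then whole sequences).
#' @param seed Integer seed.
#' @param same_gene If `TRUE` (default) the negative stays on the sequence
#'   of its source positive; otherwise the gene is drawn uniformly among all
#'   occupied genes that can hold the interval.
#' @param max_attempts Rejection-sampling cap per site. Default 1000.
#' @return `GRanges` of unbound sites, named `neg_<i>`.
#' @export
make_negatives <- function(positives, gene_bounds = NULL, seed = 1L,
                           same_gene = TRUE, max_attempts = 1000L) {
  if (is.numeric(gene_bounds) && !is.null(names(gene_bounds))) {
    gene_bounds <- data.frame(seqname = names(gene_bounds), start = 1L,
                              end = as.integer(gene_bounds))
  }
  if (is.null(gene_bounds)) {
    sl <- GenomeInfoDb_seqlengths(positives)
    if (all(is.na(sl))) stop("'gene_bounds' required (no seqlengths set)")
    gene_bounds <- data.frame(seqname = names(sl), start = 1L,
                              end = as.integer(sl))
  }
  occupied <- unique(as.character(GenomicRanges::seqnames(positives)))
  gene_bounds <- gene_bounds[gene_bounds$seqname %in% occupied, , drop = FALSE]
  set.seed(seed)
  pos_sn <- as.character(GenomicRanges::seqnames(positives))
  res <- vector("list", length(positives))
  dropped <- 0L
  for (i in seq_along(positives)) {
    w <- GenomicRanges::width(positives)[i]
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      if (same_gene) {
        gb <- gene_bounds[gene_bounds$seqname == pos_sn[i], , drop = FALSE][1L, ]
      } else {
        ok <- gene_bounds[gene_bounds$end - gene_bounds$start + 1L >= w, , drop = FALSE]
        if (!nrow(ok)) break
        gb <- ok[sample.int(nrow(ok), 1L), ]
      }
      lo <- gb$start; hi <- gb$end - w + 1L
      if (is.na(lo) || hi < lo) break
      st <- lo + floor(runif(1L) * (hi - lo + 1L))
      cand_en <- st + w - 1L
      same <- pos_sn == gb$seqname
      overlap <- any(same & GenomicRanges::start(positives) <= cand_en &
                       GenomicRanges::end(positives) >= st)
      if (!overlap) {
        res[[i]] <- data.frame(seqname = gb$seqname, start = st, end = cand_en,
                               strand = as.character(GenomicRanges::strand(positives))[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) dropped <- dropped + 1L
  }
  if (dropped > 0L) {
    warning(dropped, " negative(s) dropped: no non-overlapping placement found")
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(GenomicRanges::GRanges())
  out <- GenomicRanges::GRanges(res$seqname,
                                IRanges::IRanges(res$start, res$end),
                                strand = res$strand)
  out$name <- sprintf("neg_%04d", seq_along(out))
  out
}

GenomeInfoDb_seqlengths <- function(gr) {
  GenomeInfoDb::seqlengths(gr)
}

rna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::RNAStringSet(x)))
}

#' Build target sites with folding context
#'
#' Extends each binding site in both directions by `context` nucleotides (or
#' until the transcript end), extracts the context sequence as RNA, and
#' records the original site as the viewpoint: features will later be rooted
#' only in the viewpoint, while the surrounding context is available for
#' folding. Minus-strand sites are reverse-complemented, with the viewpoint
#' measured from the 5' end of the returned strand.
#'
#' @param sites `GRanges` of (filtered) binding sites.
#' @param fasta_source FASTA path or named character vector of sequences.
#' @param context Context extension per side in nucleotides. Default 150.
#' @return A `target_sites` data frame with columns `site_id`, `seqname`,
#'   `start`, `end`, `strand`, `ctx_start`, `ctx_end` (genomic, 1-based
#'   closed), `context` (RNA string), `vp_start`, `vp_end` (1-based within
#'   `context`), `label`, `affinity`.
#' @export
build_target_sites <- function(sites, fasta_source, context = 150L) {
  seqs <- resolve_seqs(fasta_source)
  n <- length(sites)
  sn <- as.character(GenomicRanges::seqnames(sites))
  st <- GenomicRanges::start(sites); en <- GenomicRanges::end(sites)
  strand <- as.character(GenomicRanges::strand(sites))
  lens <- nchar(seqs)[sn]
  cs <- pmax(1L, st - as.integer(context))
  ce <- pmin(lens, en + as.integer(context))
  ctx <- substr(seqs[sn], cs, ce)
  rs <- st - cs + 1L
  re <- en - cs + 1L
  ctx_len <- ce - cs + 1L
  minus <- strand == "-"
  if (any(minus)) {
    ctx[minus] <- rna_revcomp(ctx[minus])
    rs2 <- ctx_len[minus] - re[minus] + 1L
    re2 <- ctx_len[minus] - (st[minus] - cs[minus] + 1L) + 1L
    rs[minus] <- rs2; re[minus] <- re2
  }
  ids <- if (!is.null(sites$name)) as.character(sites$name)
         else sprintf("site_%04d", seq_len(n))
  ts <- data.frame(site_id = ids, seqname = sn, start = st, end = en,
                   strand = strand, ctx_start = cs, ctx_end = ce,
                   context = unname(ctx), vp_start = rs, vp_end = re,
                   label = NA_character_, affinity = NA_real_,
                   stringsAsFactors = FALSE)
  class(ts) <- c("target_sites", "data.frame")
  validate_target_sites(ts)
  ts
}

validate_target_sites <- function(ts) {
  stopifnot(all(ts$vp_start >= 1L),
            all(ts$vp_end >= ts$vp_start),
            all(ts$vp_end <= nchar(ts$context)))
  bad <- grepl("[^ACGUN]", ts$context)
  if (any(bad)) stop("context with characters outside {A,C,G,U,N}")
  invisible(ts)
}

#' Construct target sites directly from sequences
#'
#' Convenience constructor for sequences that are themselves candidate
#' binding sites (for example simulated data or probe sequences): the
#' viewpoint spans the given subregion, the whole sequence by default.
#'
#' @param seqs Named character vector of RNA/DNA sequences.
#' @param vp_start,vp_end Viewpoint bounds (1-based, closed); recycled.
#' @param label Optional `"bound"`/`"unbound"` labels; recycled.
#' @param affinity Optional numeric affinities; recycled.
#' @return A `target_sites` data frame.
#' @export
target_sites_from_seqs <- function(seqs, vp_start = 1L, vp_end = nchar(seqs),
                                   label = NA_character_, affinity = NA_real_) {
  seqs <- chartr("T", "U", toupper(seqs))
  ids <- if (is.null(names(seqs))) sprintf("seq_%04d", seq_along(seqs))
         else names(seqs)
  ts <- data.frame(site_id = ids, seqname = ids, start = vp_start,
                   end = vp_end, strand = "+", ctx_start = 1L,
                   ctx_end = nchar(seqs), context = unname(seqs),
                   vp_start = as.integer(vp_start), vp_end = as.integer(vp_end),
                   label = label, affinity = affinity,
                   stringsAsFactors = FALSE)
  class(ts) <- c("target_sites", "data.frame")
  validate_target_sites(ts)
  ts
}

#' Map a viewpoint back to genomic coordinates
#'
#' Inverse of the context construction in [build_target_sites()]: recovers
#' the genomic interval of the viewpoint of each target site.
#'
#' @param ts A `target_sites` data frame.
#' @return Data frame with `seqname`, `start`, `end`, `strand`.
#' @export
viewpoint_to_genome <- function(ts) {
  ctx_len <- nchar(ts$context)
  plus <- ts$strand != "-"
  st <- en <- integer(nrow(ts))
  st[plus] <- ts$ctx_start[plus] + ts$vp_start[plus] - 1L
  en[plus] <- ts$ctx_start[plus] + ts$vp_end[plus] - 1L
  m <- !plus
  st[m] <- ts$ctx_start[m] + (ctx_len[m] - ts$vp_end[m] + 1L) - 1L
  en[m] <- ts$ctx_start[m] + (ctx_len[m] - ts$vp_start[m] + 1L) - 1L
  data.frame(seqname = ts$seqname, start = st, end = en, strand = ts$strand)
}

#' Select UTRs by length, preferring longer
#'
#' Optional helper reproducing a 3'-UTR selection rule: keep sequences of at
#' least `min_len` and at most `max_len` nucleotides, ordered longest first.
#'
#' @param lengths Named integer vector of sequence lengths.
#' @param min_len,max_len Length bounds. Defaults 100 and 3000.
#' @return Names of the selected sequences, longest first.
#' @export
select_utrs <- function(lengths, min_len = 100L, max_len = 3000L) {
  keep <- lengths >= min_len & lengths <= max_len
  names(sort(lengths[keep], decreasing = TRUE))
}

#' Write target sites as TSV and viewpoint-marked FASTA
#'
#' The TSV holds one row per site; the FASTA encodes the viewpoint as
#' uppercase inside / lowercase outside.
#'
#' @param ts A `target_sites` data frame.
#' @param tsv,fasta Output paths (either may be `NULL` to skip).
#' @return Invisibly, `ts`.
#' @export
write_target_sites <- function(ts, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    write.table(as.data.frame(ts), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(fasta)) {
    marked <- vapply(seq_len(nrow(ts)), function(i) {
      x <- tolower(ts$context[i])
      vp <- substr(ts$context[i], ts$vp_start[i], ts$vp_end[i])
      paste0(substr(x, 1L, ts$vp_start[i] - 1L), toupper(vp),
             substr(x, ts$vp_end[i] + 1L, nchar(x)))
    }, character(1))
    writeLines(paste0(">", ts$site_id, "\n", marked), fasta)
  }
  invisible(ts)
}

#' Read target sites from the TSV written by [write_target_sites()]
#' @param tsv Path to the TSV file.
#' @return A `target_sites` data frame.
#' @export
read_target_sites <- function(tsv) {
  ts <- read.table(tsv, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c(site_id = "character", seqname = "character"))
  class(ts) <- c("target_sites", "data.frame")
  validate_target_sites(ts)
  ts
}
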