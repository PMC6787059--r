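#' Mask low-quality bases
#'
#' Replaces every base whose Phred score is below `q` with N; quality
#' strings are left unchanged.
#'
#' @param reads read data.frame (`id`, `seq`, `qual`).
#' @param q Phred threshold (default 20).
#' @return the read data.frame with masked sequences.
#' @export
mask_low_quality <- function(reads, q = 20L) {
  out <- reads
  for (i in seq_len(nrow(out))) {
    qv <- utf8ToInt(out$qual[i]) - 33L
    low <- which(qv < q)
    if (length(low)) {
      ch <- strsplit(out$seq[i], "", fixed = TRUE)[[1L]]
      ch[low] <- "N"
      out$seq[i] <- paste(ch, collapse = "")
    }
  }
  out
}

#' Parse FragSeq reads into molecule candidates
#'
#' Locates the fixed 3'-adapter anchor (allowing at most one mismatch; an N
#' counts as a mismatch) and splits each read into
#' `[barcode][UMI5][insert][UMI3][anchor]`. Reads without an anchor or with
#' an empty insert are rejected with a reason; rejections are data, not
#' errors.
#'
#' @param reads masked read data.frame.
#' @param layout list with `barcode_len`, `umi_len`, `anchor` (defaults to
#'   the package's simulation layout).
#' @return a list with `candidates` (data.frame `id`, `barcode`, `umi5`,
#'   `insert`, `umi3`) and `rejected` (data.frame `id`, `reason` in
#'   \{"no_adapter", "empty_insert"\}).
#' @export
parse_reads <- function(reads, layout = fragseq_layout()) {
  n <- nrow(reads)
  head_len <- layout$barcode_len + layout$umi_len
  min_start <- head_len + layout$umi_len + 1L   # 1-based anchor start for empty insert
  hits <- vmatchPattern(DNAString(layout$anchor), DNAStringSet(reads$seq),
                        max.mismatch = 1L, fixed = TRUE)
  astart <- vapply(seq_len(n), function(i) {
    st <- start(hits[[i]])
    st <- st[st >= min_start]
    if (length(st)) st[1L] else NA_integer_
  }, integer(1L))
  no_anchor <- is.na(astart)
  insert_len <- astart - layout$umi_len - head_len - 1L
  empty <- !no_anchor & insert_len <= 0L
  keep <- !no_anchor & !empty
  cand <- data.frame(
    id = reads$id[keep],
    barcode = substr(reads$seq[keep], 1L, layout$barcode_len),
    umi5 = substr(reads$seq[keep], layout$barcode_len + 1L, head_len),
    insert = substr(reads$seq[keep], head_len + 1L,
                    head_len + insert_len[keep]),
    umi3 = substr(reads$seq[keep], astart[keep] - layout$umi_len,
                  astart[keep] - 1L),
    stringsAsFactors = FALSE)
  rejected <- data.frame(
    id = reads$id[!keep],
    reason = ifelse(no_anchor[!keep], "no_adapter", "empty_insert"),
    stringsAsFactors = FALSE)
  list(candidates = cand, rejected = rejected)
}

# Union-find over edges for single-linkage components.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(edges[k, 1L]); b <- find(edges[k, 2L])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1L))
}

# Positionwise majority consensus over equal-length sequences with weights;
# N is ignored in the vote; ties (or all-N columns) yield N.
consensus_seq <- function(seqs, w) {
  if (length(seqs) == 1L) return(seqs)
  L <- nchar(seqs[1L])
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), nrow = length(seqs),
              byrow = TRUE)
  out <- character(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    keep <- col != "N"
    if (!any(keep)) { out[j] <- "N"; next }
    tab <- tapply(w[keep], col[keep], sum)
    top <- names(tab)[tab == max(tab)]
    out[j] <- if (length(top) == 1L) top else "N"
  }
  paste(out, collapse = "")
}

#' Collapse PCR duplicates into molecules by UMI consensus
#'
#' Groups parsed reads by the exact (UMI5, UMI3, insert length)
#' combination; within a group, single-linkage clusters join inserts at
#' Hamming distance <= 1 (N matches any base for clustering). Each cluster
#' becomes one molecule whose insert is the positionwise majority consensus
#' (ties give N) and whose `n_reads` is the cluster size.
#'
#' @param candidates data.frame from [parse_reads()].
#' @return a data.frame of molecules (`barcode`, `umi5`, `umi3`, `insert`,
#'   `n_reads`).
#' @export
cluster_consensus <- function(candidates) {
  if (nrow(candidates) == 0L)
    return(data.frame(barcode = character(), umi5 = character(),
                      umi3 = character(), insert = character(),
                      n_reads = integer(), stringsAsFactors = FALSE))
  key <- paste(candidates$umi5, candidates$umi3, nchar(candidates$insert),
               sep = "|")
  grp <- split(seq_len(nrow(candidates)), key)
  res <- vector("list", length(grp))
  for (gi in seq_along(grp)) {
    rows <- grp[[gi]]
    ins <- candidates$insert[rows]
    cnt <- table(ins)
    useq <- names(cnt)
    w <- as.numeric(cnt)
    nu <- length(useq)
    edges <- matrix(integer(), ncol = 2L)
    if (nu > 1L) {
      pairs <- utils::combn(nu, 2L)
      hit <- logical(ncol(pairs))
      for (k in seq_len(ncol(pairs)))
        hit[k] <- hamming(useq[pairs[1L, k]], useq[pairs[2L, k]],
                          n_wild = TRUE) <= 1L
      edges <- t(pairs[, hit, drop = FALSE])
    }
    comp <- uf_components(nu, edges)
    mols <- lapply(unique(comp), function(cc) {
      sel <- comp == cc
      data.frame(barcode = candidates$barcode[rows[match(useq[sel][1L], ins)]],
                 umi5 = candidates$umi5[rows[1L]],
                 umi3 = candidates$umi3[rows[1L]],
                 insert = consensus_seq(useq[sel], w[sel]),
                 n_reads = as.integer(sum(w[sel])),
                 stringsAsFactors = FALSE)
    })
    res[[gi]] <- do.call(rbind, mols)
  }
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Ungapped unique alignment of an insert to the genome
#'
#' End-to-end scan of both strands with at most `kmax` mismatches (N counts
#' as a mismatch). The insert is accepted iff exactly one (position,
#' strand) attains <= `kmax` mismatches; with `length_filter`, the insert
#' length must lie in [16, 100]. Rejection reasons: `too_short`,
#' `too_long`, `no_hit`, `ambiguous`.
#'
#' @param insert sequence over \{A,C,G,T,N\}.
#' @param genome a [genome_ref()].
#' @param kmax mismatch allowance (default 2).
#' @param length_filter apply the 16-100 nt length filter (default TRUE).
#' @return a list: either `list(status = "unique", contig, start, end,
#'   strand, mismatches, insert_len)` or `list(status = <reason>)`.
#' @export
align_unique <- function(insert, genome, kmax = 2L, length_filter = TRUE) {
  len <- nchar(insert)
  if (length_filter) {
    if (len < 16L) return(list(status = "too_short"))
    if (len > 100L) return(list(status = "too_long"))
  }
  hits <- NULL
  for (contig in names(genome$seqs)) {
    subj <- DNAString(genome$seqs[[contig]])
    p <- DNAString(insert)
    fwd <- matchPattern(p, subj, max.mismatch = kmax, fixed = TRUE)
    rev <- matchPattern(reverseComplement(p), subj, max.mismatch = kmax,
                        fixed = TRUE)
    if (length(fwd))
      hits <- rbind(hits, data.frame(contig = contig,
                                     start = start(fwd) - 1L,
                                     end = end(fwd), strand = "+",
                                     stringsAsFactors = FALSE))
    if (length(rev))
      hits <- rbind(hits, data.frame(contig = contig,
                                     start = start(rev) - 1L,
                                     end = end(rev), strand = "-",
                                     stringsAsFactors = FALSE))
  }
  if (is.null(hits) || nrow(hits) == 0L) return(list(status = "no_hit"))
  if (nrow(hits) > 1L) return(list(status = "ambiguous"))
  h <- hits[1L, ]
  ref <- extract_seq_many(genome, h$contig, h$start, h$end, h$strand)
  list(status = "unique", contig = h$contig, start = h$start, end = h$end,
       strand = h$strand, mismatches = hamming(insert, ref),
       insert_len = len)
}

#' Align a set of molecules and build the fragment table
#'
#' Applies [align_unique()] to every molecule insert (deduplicating
#' identical insert strings for speed) and aggregates accepted hits by
#' (interval, strand): `abundance` counts molecules, so the table total
#' equals the number of uniquely aligned molecules.
#'
#' @param molecules molecule data.frame from [cluster_consensus()] (only
#'   the `insert` column is required).
#' @param genome a [genome_ref()].
#' @param kmax,length_filter passed to [align_unique()].
#' @return a list with `table` (data.frame of class `"fragment_table"`:
#'   `contig`, `start`, `end`, `strand`, `length`, `abundance`,
#'   `mismatches`) and `rejections` (named counts by reason).
#' @export
align_molecules <- function(molecules, genome, kmax = 2L,
                            length_filter = TRUE) {
  ins <- molecules$insert
  uniq <- unique(ins)
  res <- lapply(uniq, align_unique, genome = genome, kmax = kmax,
                length_filter = length_filter)
  names(res) <- uniq
  status <- vapply(res, `[[`, "", "status")
  per_mol <- res[match(ins, uniq)]
  ok <- status[match(ins, uniq)] == "unique"
  rej <- table(factor(status[match(ins, uniq)][!ok],
                      levels = c("too_short", "too_long", "no_hit",
                                 "ambiguous")))
  hits <- do.call(rbind, lapply(per_mol[ok], function(h)
    data.frame(contig = h$contig, start = h$start, end = h$end,
               strand = h$strand, length = h$insert_len,
               mismatches = h$mismatches, stringsAsFactors = FALSE)))
  list(table = build_fragment_table(hits), rejections = c(rej))
}

#' Aggregate fragment hits into a fragment table
#'
#' @param hits data.frame of accepted hits (`contig`, `start`, `end`,
#'   `strand`, `length`, `mismatches`); one row per molecule.
#' @return data.frame of class `"fragment_table"` with per-interval
#'   `abundance` (molecule counts); total abundance equals `nrow(hits)`.
#' @export
build_fragment_table <- function(hits) {
  empty <- data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), abundance = integer(),
                      mismatches = numeric(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) {
    class(empty) <- c("fragment_table", "data.frame")
    return(empty)
  }
  key <- paste(hits$contig, hits$start, hits$end, hits$strand, sep = "|")
  agg <- split(seq_len(nrow(hits)), key)
  out <- do.call(rbind, lapply(agg, function(rows) {
    data.frame(contig = hits$contig[rows[1L]], start = hits$start[rows[1L]],
               end = hits$end[rows[1L]], strand = hits$strand[rows[1L]],
               length = hits$length[rows[1L]],
               abundance = length(rows),
               mismatches = mean(hits$mismatches[rows]),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$contig, out$start, out$end, out$strand), ]
  row.names(out) <- NULL
  class(out) <- c("fragment_table", "data.frame")
  out
}

#' Run the full FragSeq read-processing pipeline
#'
#' Chains quality masking, adapter/UMI parsing, PCR-duplicate consensus
#' clustering and unique ungapped alignment, with read-conservation
#' accounting at every stage.
#'
#' @param reads raw read data.frame.
#' @param genome a [genome_ref()].
#' @param layout adapter layout (see [parse_reads()]).
#' @param qmask Phred masking threshold.
#' @param kmax,length_filter alignment parameters.
#' @return a list with `table` (fragment table), `molecules`, and
#'   `accounting` (named counts: reads in, parsed, rejected by reason,
#'   molecules, aligned, alignment rejections by reason).
#' @export
fragseq_pipeline <- function(reads, genome, layout = fragseq_layout(),
                             qmask = 20L, kmax = 2L, length_filter = TRUE) {
  masked <- mask_low_quality(reads, qmask)
  parsed <- parse_reads(masked, layout)
  mols <- cluster_consensus(parsed$candidates)
  aln <- align_molecules(mols, genome, kmax = kmax,
                         length_filter = length_filter)
  acct <- c(reads_in = nrow(reads),
            parsed = nrow(parsed$candidates),
            stats::setNames(as.integer(table(factor(parsed$rejected$reason,
                            levels = c("no_adapter", "empty_insert")))),
                            c("no_adapter", "empty_insert")),
            molecules = nrow(mols),
            aligned = sum(aln$table$abundance),
            aln$rejections)
  list(table = aln$table, molecules = mols, accounting = acct)
}
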