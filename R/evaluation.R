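as_reference_set <- function(reference) {
  if (inherits(reference, "wgp_genome")) {
    return(c(genome = reference$sequence))
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    return(out)
  }
  stopifnot(is.character(reference))
  if (is.null(names(reference))) {
    names(reference) <- sprintf("ref_%03d", seq_along(reference))
  }
  reference
}

#' Map tags to reference sequence by exact full-length matching
#'
#' Places each tag on both strands of every reference sequence, keeping only
#' full-length, full-identity placements. All placements are recorded, so a
#' repeat-derived tag may map to several loci. The EcoRI site coordinate of
#' each placement (0-based start of the GAATTC site) is derived from the
#' strand, so the two tags flanking one site share a site coordinate.
#'
#' @param tags character vector of tag sequences, or a data.frame with a
#'   `tag_sequence` column.
#' @param reference named character vector of reference sequences, a
#'   `DNAStringSet`, or a `wgp_genome`.
#' @return a `wgp_alignment` data.frame: `tag_sequence`, `reference_id`,
#'   `position` (0-based start of the match on the forward strand), `strand`,
#'   `site` (0-based EcoRI site coordinate). Attribute `reference_lengths`
#'   holds the reference sequence lengths.
#' @export
map_tags_to_reference <- function(tags, reference) {
  if (is.data.frame(tags)) tags <- tags$tag_sequence
  tags <- unique(as.character(tags))
  refs <- as_reference_set(reference)
  if (length(refs) == 0L || any(nchar(refs) == 0L)) {
    stop("reference must be non-empty", call. = FALSE)
  }
  out <- list()
  for (w in sort(unique(nchar(tags)))) {
    grp <- tags[nchar(tags) == w]
    pd <- Biostrings::PDict(grp)
    for (ri in seq_along(refs)) {
      subj <- Biostrings::DNAString(refs[[ri]])
      L <- length(subj)
      fwd <- Biostrings::matchPDict(pd, subj)
      nf <- lengths(fwd)
      if (sum(nf)) {
        st <- unlist(lapply(fwd, BiocGenerics::start), use.names = FALSE)
        out[[length(out) + 1L]] <- data.frame(
          tag_sequence = rep(grp, nf), reference_id = names(refs)[ri],
          position = st - 1L, strand = "+")
      }
      rev <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      nr <- lengths(rev)
      if (sum(nr)) {
        st <- unlist(lapply(rev, BiocGenerics::start), use.names = FALSE)
        en <- st + w - 1L
        out[[length(out) + 1L]] <- data.frame(
          tag_sequence = rep(grp, nr), reference_id = names(refs)[ri],
          position = L - en, strand = "-")
      }
    }
  }
  aln <- if (length(out)) do.call(rbind, out) else
    data.frame(tag_sequence = character(0), reference_id = character(0),
               position = integer(0), strand = character(0))
  w <- nchar(aln$tag_sequence)
  aln$site <- ifelse(aln$strand == "+", aln$position - 1L,
                     aln$position + w - 5L)
  aln <- aln[order(aln$reference_id, aln$position, aln$tag_sequence), ,
             drop = FALSE]
  rownames(aln) <- NULL
  attr(aln, "reference_lengths") <-
    stats::setNames(nchar(refs), names(refs))
  class(aln) <- c("wgp_alignment", "data.frame")
  aln
}

# per-clone mapped-tag fraction and majority reference placement
bac_placements <- function(assignment, alignment) {
  df <- assignment$assignment
  dt <- as.data.table(df)
  aln <- as.data.table(as.data.frame(alignment))
  tagpos <- unique(aln[, .(tag_sequence, reference_id, position)])
  hits <- merge(dt, tagpos, by = "tag_sequence", allow.cartesian = TRUE)
  per_clone <- dt[, .(n_tags = uniqueN(tag_sequence)), by = clone_id]
  if (nrow(hits)) {
    mapped <- hits[, .(n_mapped = uniqueN(tag_sequence)), by = clone_id]
    # majority reference, then the median position on it
    byref <- hits[, .N, by = .(clone_id, reference_id)]
    setorder(byref, clone_id, -N, reference_id)
    major <- byref[, .SD[1L], by = clone_id][, .(clone_id, reference_id)]
    pos <- merge(hits, major, by = c("clone_id", "reference_id"))[
      , .(position = as.numeric(stats::median(position))),
      by = .(clone_id, reference_id)]
  } else {
    mapped <- data.table(clone_id = character(0), n_mapped = integer(0))
    pos <- data.table(clone_id = character(0), reference_id = character(0),
                      position = numeric(0))
  }
  res <- merge(per_clone, mapped, by = "clone_id", all.x = TRUE)
  res[is.na(n_mapped), n_mapped := 0L]
  res <- merge(res, pos, by = "clone_id", all.x = TRUE)
  res[, fraction := n_mapped / n_tags]
  as.data.frame(res)
}

#' Classify BACs as matched or unmatched against a reference
#'
#' A clone is "matched" when strictly more than `threshold` of its assigned
#' tags have at least one reference placement.
#'
#' @param assignment a `wgp_assignment`.
#' @param alignment a `wgp_alignment` from [map_tags_to_reference()].
#' @param threshold mapped-tag fraction above which a clone is matched.
#' @return data.frame `clone_id`, `n_tags`, `n_mapped`, `fraction`,
#'   `reference_id`, `position`, `matched`.
#' @export
classify_bacs <- function(assignment, alignment, threshold = 0.5) {
  res <- bac_placements(assignment, alignment)
  res$matched <- res$fraction > threshold
  res
}

#' Detect chimeric contigs against a reference
#'
#' A contig with at least two matched BACs is chimeric when the placements of
#' its matched BACs fall on two or more reference sequences, or when
#' consecutive placements on one reference are separated by more than
#' `slack_bp`. The rate is normalised per 10 Mb of reference.
#'
#' @param map a `wgp_map`.
#' @param assignment a `wgp_assignment`.
#' @param alignment a `wgp_alignment`.
#' @param slack_bp maximum within-contig placement gap before the contig is
#'   split into discontiguous clusters (default twice a typical 138 kb clone).
#' @param threshold matched-BAC threshold, see [classify_bacs()].
#' @return list `chimeric` (contig ids), `n_evaluated`, `rate_per_10mb`,
#'   `per_contig` (data.frame).
#' @export
detect_chimeras <- function(map, assignment, alignment, slack_bp = 276000,
                            threshold = 0.5) {
  cls <- classify_bacs(assignment, alignment, threshold)
  per <- lapply(map$contigs, function(ct) {
    sub <- cls[cls$clone_id %in% ct$clones & cls$matched, , drop = FALSE]
    if (nrow(sub) < 2L) {
      return(data.frame(contig_id = ct$contig_id, n_matched = nrow(sub),
                        evaluated = FALSE, chimeric = FALSE))
    }
    nref <- length(unique(sub$reference_id))
    maxgap <- if (nref > 1L) Inf else {
      p <- sort(sub$position)
      if (length(p) > 1L) max(diff(p)) else 0
    }
    data.frame(contig_id = ct$contig_id, n_matched = nrow(sub),
               evaluated = TRUE, chimeric = nref > 1L || maxgap > slack_bp)
  })
  per <- do.call(rbind, per) %||%
    data.frame(contig_id = character(0), n_matched = integer(0),
               evaluated = logical(0), chimeric = logical(0))
  ref_mb <- sum(attr(alignment, "reference_lengths")) / 1e6
  chim <- per$contig_id[per$chimeric]
  list(chimeric = chim, n_evaluated = sum(per$evaluated),
       rate_per_10mb = if (ref_mb > 0) length(chim) / (ref_mb / 10) else NA_real_,
       per_contig = per)
}

#' Percentage of mis-assembled BACs
#'
#' Among the clones of contigs that could be evaluated against the reference
#' (contigs with at least two matched BACs), the percentage whose mapped-tag
#' fraction falls below `threshold`, i.e. clones placed in a contig that does
#' not correspond to their genomic origin.
#'
#' @inheritParams detect_chimeras
#' @return list `pct`, `n_evaluated`, `n_misassembled`, `clones`.
#' @export
misassembled_fraction <- function(map, assignment, alignment, threshold = 0.5) {
  cls <- classify_bacs(assignment, alignment, threshold)
  evaluable <- vapply(map$contigs, function(ct) {
    sum(cls$matched[cls$clone_id %in% ct$clones]) >= 2L
  }, logical(1))
  clones <- unlist(lapply(map$contigs[evaluable], `[[`, "clones"),
                   use.names = FALSE)
  sub <- cls[cls$clone_id %in% clones, , drop = FALSE]
  bad <- sub$clone_id[!sub$matched]
  list(pct = if (nrow(sub)) 100 * length(bad) / nrow(sub) else NA_real_,
       n_evaluated = nrow(sub), n_misassembled = length(bad), clones = bad)
}

#' Calibrate the consensus-band (CB) unit against reference sequence
#'
#' For every contig with at least two mapped tags, the ratio between its
#' spanned reference length (kb) and its consensus length in CB units; the
#' mean and standard deviation across contigs estimate the kb size of one CB
#' unit.
#'
#' @inheritParams detect_chimeras
#' @return list `mean_kb`, `sd_kb`, `per_contig`.
#' @export
cb_unit_size <- function(map, assignment, alignment) {
  dt <- as.data.table(assignment$assignment)
  aln <- as.data.table(as.data.frame(alignment))
  hits <- merge(dt, aln[, .(tag_sequence, reference_id, site)],
                by = "tag_sequence", allow.cartesian = TRUE)
  per <- lapply(map$contigs, function(ct) {
    sub <- hits[clone_id %in% ct$clones]
    if (nrow(sub) == 0L) return(NULL)
    byref <- sub[, .N, by = reference_id]
    setorder(byref, -N, reference_id)
    sub <- sub[reference_id == byref$reference_id[1L]]
    if (uniqueN(sub$tag_sequence) < 2L) return(NULL)
    span_kb <- (max(sub$site) - min(sub$site)) / 1000
    data.frame(contig_id = ct$contig_id, span_kb = span_kb,
               length_cb = ct$length_cb, kb_per_cb = span_kb / ct$length_cb)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0L) {
    stop("no contig with at least two mapped tags", call. = FALSE)
  }
  list(mean_kb = mean(per$kb_per_cb),
       sd_kb = if (nrow(per) > 1L) sd(per$kb_per_cb) else 0,
       per_contig = per)
}

#' C1^2/C2 chimera score of a contig
#'
#' C1 is the fraction of clone pairs within the contig sharing at least one
#' tag; C2 is the average tag density (total clone tags over the consensus
#' length in CB units). Chimeric contigs tend to have low C1 relative to
#' their density, so lower scores are more suspicious; the decision threshold
#' is genome-dependent and deliberately left to the caller.
#'
#' @param contig one element of `map$contigs`.
#' @param assignment a `wgp_assignment`.
#' @return list `c1`, `c2`, `score`.
#' @export
chimera_score_c1c2 <- function(contig, assignment) {
  clones <- contig$clones
  if (length(clones) < 2L) stop("contig must have >= 2 clones", call. = FALSE)
  sets <- split(assignment$assignment$tag_sequence,
                assignment$assignment$clone_id)[clones]
  cmb <- utils::combn(length(clones), 2L)
  share <- mapply(function(i, j) length(intersect(sets[[i]], sets[[j]])) > 0L,
                  cmb[1L, ], cmb[2L, ])
  c1 <- mean(share)
  c2 <- sum(lengths(sets)) / contig$length_cb
  if (c2 == 0) stop("undefined score: contig has no tags", call. = FALSE)
  list(c1 = c1, c2 = c2, score = c1^2 / c2)
}

interval_coverage_prefix <- function(starts, ends, L) {
  delta <- numeric(L + 1L)
  for (i in seq_along(starts)) {
    a <- max(0L, starts[i]); b <- min(L, ends[i])
    if (b > a) {
      delta[a + 1L] <- delta[a + 1L] + 1
      if (b < L) delta[b + 1L] <- delta[b + 1L] - 1
    }
  }
  cum <- cumsum(delta)[seq_len(L)]
  c(0, cumsum(pmin(cum, 1)))  # prefix covered-bp, length L + 1
}

#' Sliding-window tag landscape versus TE content
#'
#' Counts placed tags and EcoRI sites, and the transposable-element coverage
#' percentage, in sliding windows along one reference sequence, then reports
#' the Pearson correlation between tag counts and TE percentage across
#' windows. Windows are anchored at 0 and a trailing partial window is
#' dropped. A zero-variance column yields r = 0 with a warning rather than
#' NaN.
#'
#' @param reference a single reference sequence (string or `wgp_genome`).
#' @param alignment a `wgp_alignment` (placements on that reference).
#' @param te_intervals data.frame `start`, `end` (0-based half-open).
#' @param window,step window and step sizes in bp (`window >= step`).
#' @return list `windows` (data.frame `start`, `end`, `n_tags`,
#'   `n_ecori_sites`, `te_pct`), `r`, `p_value`.
#' @export
tag_landscape <- function(reference, alignment, te_intervals,
                          window = 50000L, step = 10000L) {
  if (window < step) stop("`window` must be >= `step`", call. = FALSE)
  seqstr <- genome_sequence(reference)
  L <- nchar(seqstr)
  if (L < window) stop("reference shorter than one window", call. = FALSE)
  starts <- seq(0L, L - window, by = step)
  sites <- find_sites(seqstr, ECORI_SITE)
  aln <- as.data.frame(alignment)
  tagpos <- sort(aln$position)
  cov <- interval_coverage_prefix(te_intervals$start, te_intervals$end, L)
  count_in <- function(sorted, a, b) {
    findInterval(b - 0.5, sorted) - findInterval(a - 0.5, sorted)
  }
  win <- data.frame(
    start = starts, end = starts + window,
    n_tags = vapply(starts, function(a)
      count_in(tagpos, a, a + window), numeric(1)),
    n_ecori_sites = vapply(starts, function(a)
      count_in(sites, a, a + window), numeric(1)),
    te_pct = vapply(starts, function(a)
      100 * (cov[a + window + 1L] - cov[a + 1L]) / window, numeric(1)))
  if (sd(win$n_tags) == 0 || sd(win$te_pct) == 0) {
    warning("zero variance in a landscape column; correlation set to 0")
    return(list(windows = win, r = 0, p_value = NA_real_))
  }
  ct <- cor.test(win$n_tags, win$te_pct)
  list(windows = win, r = unname(ct$estimate), p_value = ct$p.value)
}

#' Distances between consecutive tag placements
#'
#' Distances are measured between the EcoRI site coordinates of consecutive
#' unique tag placements along each reference, so the two tags flanking one
#' EcoRI site are at distance 0. Site-level tag multiplicity is tallied over
#' all EcoRI sites of the reference.
#'
#' @param alignment a `wgp_alignment`.
#' @param reference the reference sequences the alignment was computed on.
#' @return list `mean`, `sd`, `median`, `max`, `min`, `n_distances`,
#'   `pct_sites_no_tag`, `pct_sites_one_tag`, `pct_sites_two_tags`.
#' @export
inter_tag_distances <- function(alignment, reference) {
  refs <- as_reference_set(reference)
  aln <- as.data.frame(alignment)
  dists <- numeric(0)
  n_sites <- 0L
  mult <- integer(3)  # sites with 0 / 1 / 2+ tags
  for (ri in names(refs)) {
    sites <- find_sites(refs[[ri]], ECORI_SITE)
    n_sites <- n_sites + length(sites)
    sub <- aln[aln$reference_id == ri, , drop = FALSE]
    pos <- sort(sub$site)
    if (length(pos) >= 2L) dists <- c(dists, diff(pos))
    cnt <- as.integer(table(sub$site)[as.character(sites)])
    cnt[is.na(cnt)] <- 0L
    mult <- mult + c(sum(cnt == 0L), sum(cnt == 1L), sum(cnt >= 2L))
  }
  if (length(dists) == 0L) stop("need >= 2 placements", call. = FALSE)
  list(mean = mean(dists), sd = if (length(dists) > 1L) sd(dists) else 0,
       median = median(dists), max = max(dists), min = min(dists),
       n_distances = length(dists),
       pct_sites_no_tag = 100 * mult[1] / n_sites,
       pct_sites_one_tag = 100 * mult[2] / n_sites,
       pct_sites_two_tags = 100 * mult[3] / n_sites)
}

#' N90 / L90 contiguity metrics against a fixed reference length
#'
#' L90 is the minimum number of pieces (taken longest first) whose summed
#' length covers at least 90 percent of `reference_total`; N90 is the length of the
#' last piece counted. When the pieces sum to less than 90 percent of the
#' reference, both are `NA` and `reached` is `FALSE`.
#'
#' @param lengths piece lengths (bp).
#' @param reference_total reference length (bp) used as the fixed denominator.
#' @return list `n90`, `l90`, `reached`.
#' @export
n90_l90 <- function(lengths, reference_total) {
  if (length(lengths) == 0L) stop("empty length list", call. = FALSE)
  if (reference_total <= 0) stop("`reference_total` must be > 0", call. = FALSE)
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(s)
  target <- 0.9 * reference_total
  k <- which(cum >= target)
  if (length(k) == 0L) return(list(n90 = NA_real_, l90 = NA_integer_,
                                   reached = FALSE))
  list(n90 = s[k[1L]], l90 = k[1L], reached = TRUE)
}

#' Fraction of distinct k-mers occurring exactly once
#'
#' Canonical (strand-collapsed) k-mer counting over a set of sequences;
#' k-mers containing non-ACGT characters are skipped. High uniqueness at the
#' tag length indicates that tags of that length discriminate loci well.
#'
#' @param sequences character vector of sequences.
#' @param k k-mer size (the relevant sweep for tag design is roughly 15-70).
#' @return fraction in `[0, 1]` of distinct canonical k-mers seen exactly
#'   once.
#' @export
kmer_uniqueness <- function(sequences, k) {
  stopifnot(k >= 1L)
  sequences <- toupper(sequences)
  if (all(nchar(sequences) < k)) {
    stop("k exceeds the longest sequence", call. = FALSE)
  }
  kmers <- unlist(lapply(sequences, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  tab <- data.table(k = canon)[, .N, by = k]
  sum(tab$N == 1L) / nrow(tab)
}

#' Gap percentage of an assembly
#'
#' Internal mode (`scaffolds` given): percentage of N bases over the total
#' scaffold length. Reference mode (`placements` + `reference_length` given):
#' percentage of the reference not covered by any placed piece.
#'
#' @param scaffolds character vector of scaffold sequences (may contain N).
#' @param placements data.frame `start`, `end` (0-based half-open reference
#'   coordinates of placed pieces).
#' @param reference_length reference length (bp) for reference mode.
#' @return gap percentage in `[0, 100]`.
#' @export
gap_percentage <- function(scaffolds = NULL, placements = NULL,
                           reference_length = NULL) {
  if (!is.null(scaffolds)) {
    total <- sum(nchar(scaffolds))
    nn <- sum(vapply(scaffolds, function(s)
      sum(charToRaw(toupper(s)) == charToRaw("N")), numeric(1)))
    return(100 * nn / total)
  }
  stopifnot(!is.null(placements), !is.null(reference_length))
  cov <- interval_coverage_prefix(placements$start, placements$end,
                                  reference_length)
  100 * (reference_length - cov[reference_length + 1L]) / reference_length
}
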