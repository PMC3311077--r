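#' Place tags on draft sequence contigs
#'
#' Exact full-length matching of tags on both strands of the sequence
#' contigs (see [map_tags_to_reference()]). Multi-placement tags are kept and
#' marked, since repeat-derived tags must not anchor links on their own.
#'
#' @param tags character vector of tag sequences or data.frame with
#'   `tag_sequence`.
#' @param sequence_contigs named character vector (or `DNAStringSet`) of
#'   draft contigs/scaffolds.
#' @return data.frame `tag_sequence`, `contig_id`, `position`, `strand`,
#'   `site_id` (restriction-site identity on the contig), `n_hits` (total
#'   placements of the tag), `multi` flag.
#' @export
place_tags <- function(tags, sequence_contigs) {
  aln <- map_tags_to_reference(tags, sequence_contigs)
  df <- as.data.frame(aln)
  names(df)[names(df) == "reference_id"] <- "contig_id"
  df$site_id <- paste(df$contig_id, df$site, sep = ":")
  nh <- table(df$tag_sequence)
  df$n_hits <- as.integer(nh[df$tag_sequence])
  df$multi <- df$n_hits > 1L
  attr(df, "reference_lengths") <- attr(aln, "reference_lengths")
  df
}

# Merge a unit's ordered element list (bins of sequence-contig ids) into an
# existing ordered list, using shared members as anchors. The incoming order
# is reversed when its anchors run against the existing order; new bins are
# inserted at the position implied by the surrounding anchors.
stitch_orders <- function(base, els) {
  if (length(base) == 0L) return(els)
  anchor_of <- function(e) {
    hit <- which(vapply(base, function(b) any(e %in% b), logical(1)))
    if (length(hit)) hit[1L] else NA_integer_
  }
  match_idx <- vapply(els, anchor_of, integer(1))
  sh <- which(!is.na(match_idx))
  if (length(sh) == 0L) return(c(base, els))
  if (length(sh) >= 2L &&
      stats::cor(seq_along(sh), match_idx[sh], method = "spearman") < 0) {
    els <- rev(els)
    match_idx <- rev(match_idx)
    sh <- which(!is.na(match_idx))
  }
  if (length(sh) == 1L) {
    # one shared bin: the incoming unit extends outward from that anchor,
    # on the side of the base away from the base's remaining elements
    tgt <- match_idx[sh]
    pre <- els[seq_len(sh - 1L)]
    post <- if (sh < length(els)) els[(sh + 1L):length(els)] else list()
    merged <- list(union(base[[tgt]], els[[sh]]))
    outward_left <- if (length(post)) rev(post) else pre
    outward_right <- if (length(post)) post else rev(pre)
    if (tgt <= (length(base) + 1L) / 2) {
      return(c(outward_left, head(base, tgt - 1L), merged,
               base[seq_along(base) > tgt]))
    }
    return(c(head(base, tgt - 1L), merged,
             base[seq_along(base) > tgt], outward_right))
  }
  out <- list()
  pending <- list()
  bi <- 1L
  for (kk in seq_along(els)) {
    if (is.na(match_idx[kk])) {
      pending <- c(pending, els[kk])
    } else {
      tgt <- match_idx[kk]
      while (bi < tgt) { out <- c(out, base[bi]); bi <- bi + 1L }
      out <- c(out, pending)
      pending <- list()
      if (bi == tgt) {
        merged <- union(base[[tgt]], els[[kk]])
        out <- c(out, list(merged))
        bi <- bi + 1L
      } else {
        # anchor already flushed (out-of-order repeat); merge its extras
        extra <- setdiff(els[[kk]], unlist(out))
        if (length(extra)) out <- c(out, list(extra))
      }
    }
  }
  while (bi <= length(base)) { out <- c(out, base[bi]); bi <- bi + 1L }
  c(out, pending)
}

# clone placement centres along each WGP contig's CB map, plus singleton
# pseudo-units (one clone, centre 0)
wgp_units <- function(map) {
  res <- lapply(map$contigs, function(ct) {
    pl <- ct$placements
    data.frame(unit = ct$contig_id, clone_id = pl$clone_id,
               centre = (pl$start_slot + pl$end_slot) / 2)
  })
  sgl <- if (length(map$singletons)) {
    data.frame(unit = paste0("sgl_", map$singletons),
               clone_id = map$singletons, centre = 0)
  } else NULL
  do.call(rbind, c(res, list(sgl)))
}

#' Link sequence contigs into superscaffolds via WGP tags
#'
#' A sequence contig is eligible for linking when at least `min_tags`
#' distinct tags from at least `min_sites` distinct restriction sites hit it
#' from a single WGP contig (or singleton clone). Along one WGP contig,
#' sequence contigs are ordered by the mean CB-map position of the clones
#' carrying their placed tags (exact intra-BAC tag positions are unknown, so
#' clone placements are the position proxy); contigs with indistinguishable
#' proxy positions are grouped into unordered bins. Sequence contigs hit by
#' several WGP contigs bridge those contigs into longer superscaffolds;
#' bridging proceeds to fixpoint, and incompatible bridges are dropped
#' weakest-first (fewest supporting tags; ties drop both) and reported as
#' conflicts.
#'
#' @param placements from [place_tags()].
#' @param map a `wgp_map`.
#' @param assignment a `wgp_assignment` sharing the tag space.
#' @param min_tags,min_sites eligibility thresholds.
#' @return list `superscaffolds` (list of `superscaffold` objects),
#'   `support` (per contig-unit evidence), `conflicts` (data.frame).
#' @export
link_contigs <- function(placements, map, assignment, min_tags = 2L,
                         min_sites = 2L) {
  units <- wgp_units(map)
  if (is.null(units) || nrow(placements) == 0L) {
    return(list(superscaffolds = list(), support = NULL,
                conflicts = data.frame()))
  }
  adt <- as.data.table(assignment$assignment)
  pdt <- as.data.table(placements)
  udt <- as.data.table(units)
  ev <- merge(pdt, adt, by = "tag_sequence", allow.cartesian = TRUE)
  ev <- merge(ev, udt, by = "clone_id", allow.cartesian = TRUE)
  support <- ev[, .(
    n_tags = uniqueN(tag_sequence),
    n_sites = uniqueN(site_id),
    proxy = mean(tapply(centre, tag_sequence, mean)),
    seq_pos = mean(position),
    strand_plus = mean(strand == "+")),
    by = .(contig_id, unit)]
  elig <- support[n_tags >= min_tags & n_sites >= min_sites]
  if (nrow(elig) == 0L) {
    return(list(superscaffolds = list(), support = as.data.frame(support),
                conflicts = data.frame()))
  }
  ## per-unit element order: bins of sequence contigs tied on proxy position
  unit_order <- function(u) {
    sub <- elig[unit == u]
    setorder(sub, proxy, contig_id)
    grp <- cumsum(c(TRUE, diff(sub$proxy) > 1e-9))
    split(sub$contig_id, grp)
  }
  unit_ids <- unique(elig$unit)
  orders <- lapply(unit_ids, unit_order)
  names(orders) <- unit_ids
  ## bridges: sequence contigs eligible to >= 2 units
  bridge_tab <- elig[, .(n_units = .N), by = contig_id][n_units >= 2L]
  conflicts <- list()
  edges <- NULL
  if (nrow(bridge_tab)) {
    bs <- elig[contig_id %in% bridge_tab$contig_id]
    # order the units a bridge touches by the tag positions on the sequence
    eb <- lapply(split(bs, bs$contig_id), function(b) {
      setorder(b, seq_pos, unit)
      if (nrow(b) < 2L) return(NULL)
      data.frame(bridge = b$contig_id[1L],
                 from = b$unit[-nrow(b)], to = b$unit[-1L],
                 weight = pmin(b$n_tags[-nrow(b)], b$n_tags[-1L]))
    })
    edges <- do.call(rbind, eb)
  }
  ## chain units with the accepted bridge edges (paths only; degree <= 2,
  ## no cycles); weaker conflicting edges are dropped and reported
  deg <- stats::setNames(integer(length(unit_ids)), unit_ids)
  parent <- uf_new(length(unit_ids))
  uidx <- stats::setNames(seq_along(unit_ids), unit_ids)
  accepted <- list()
  if (!is.null(edges) && nrow(edges)) {
    edges <- edges[order(-edges$weight, edges$bridge), , drop = FALSE]
    dup <- duplicated(paste(pmin(edges$from, edges$to),
                            pmax(edges$from, edges$to)))
    edges <- edges[!dup, , drop = FALSE]
    for (r in seq_len(nrow(edges))) {
      a <- edges$from[r]; b <- edges$to[r]
      ok <- deg[a] < 2L && deg[b] < 2L &&
        uf_find(parent, uidx[a]) != uf_find(parent, uidx[b])
      if (ok) {
        deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
        parent <- uf_union(parent, uidx[a], uidx[b])
        accepted[[length(accepted) + 1L]] <- edges[r, ]
      } else {
        conflicts[[length(conflicts) + 1L]] <-
          cbind(edges[r, ], reason = "incompatible_bridge")
      }
    }
  }
  accepted <- do.call(rbind, accepted)
  ## walk each chain of units, stitching per-unit element orders via the
  ## bridge contigs shared between neighbouring units
  comp <- split(unit_ids, vapply(unit_ids, function(u)
    uf_find(parent, uidx[u]), integer(1)))
  ssc <- lapply(seq_along(comp), function(k) {
    us <- comp[[k]]
    if (length(us) > 1L) {
      adj <- accepted[accepted$from %in% us | accepted$to %in% us, ,
                      drop = FALSE]
      d <- table(c(adj$from, adj$to))
      start <- names(d)[d == 1L][1L]
      chain <- start; cur <- start; prev <- ""
      while (length(chain) < length(us)) {
        nb <- setdiff(c(adj$to[adj$from == cur], adj$from[adj$to == cur]),
                      c(prev, chain))
        if (length(nb) == 0L) break
        prev <- cur; cur <- nb[1L]; chain <- c(chain, cur)
      }
      us <- chain
    }
    elements <- list()
    for (u in us) elements <- stitch_orders(elements, orders[[u]])
    sup <- as.data.frame(elig[unit %in% us])
    structure(list(id = sprintf("ssc_%03d", k), units = us,
                   elements = elements, support = sup),
              class = "superscaffold")
  })
  list(superscaffolds = ssc, support = as.data.frame(support),
       conflicts = do.call(rbind, conflicts) %||% data.frame())
}

#' @export
print.superscaffold <- function(x, ...) {
  cat(sprintf("superscaffold %s: %d elements (%d binned) over units %s\n",
              x$id, length(x$elements),
              sum(lengths(x$elements) > 1L),
              paste(x$units, collapse = ",")))
  invisible(x)
}

#' Assign sequence scaffolds to their BAC (and physical contig) of origin
#'
#' A scaffold is assigned to every BAC contributing at least `min_tags`
#' distinct placed tags. When a physical map is supplied, the BAC's contig
#' provides the physical contig of origin, which routes scaffolds from
#' pooled sequencing of unrelated contigs back to their source.
#'
#' @param placements from [place_tags()].
#' @param assignment a `wgp_assignment`.
#' @param min_tags minimum distinct supporting tags per (scaffold, BAC).
#' @param map optional `wgp_map` used to annotate the physical contig.
#' @return list `assigned` (data.frame `contig_id`, `clone_id`, `n_tags`,
#'   optional `physical_contig`), `unassigned` (scaffold ids with no
#'   qualifying BAC).
#' @export
assign_scaffolds_to_bacs <- function(placements, assignment, min_tags = 2L,
                                     map = NULL) {
  pdt <- as.data.table(placements)
  adt <- as.data.table(assignment$assignment)
  ev <- merge(unique(pdt[, .(tag_sequence, contig_id)]), adt,
              by = "tag_sequence", allow.cartesian = TRUE)
  cnt <- ev[, .(n_tags = uniqueN(tag_sequence)), by = .(contig_id, clone_id)]
  hit <- cnt[n_tags >= min_tags]
  out <- as.data.frame(hit)
  if (!is.null(map)) {
    lut <- do.call(rbind, lapply(map$contigs, function(ct)
      data.frame(clone_id = ct$clones, physical_contig = ct$contig_id)))
    if (!is.null(lut)) out <- merge(out, lut, by = "clone_id", all.x = TRUE)
    out$physical_contig[is.na(out$physical_contig)] <- "singleton"
  }
  # scaffolds with no placements at all are still reported as unassigned
  all_ids <- names(attr(placements, "reference_lengths")) %||%
    unique(pdt$contig_id)
  list(assigned = out[order(out$contig_id, out$clone_id), , drop = FALSE],
       unassigned = setdiff(all_ids, unique(out$contig_id)))
}

#' Score a superscaffold against the true piece order
#'
#' Computes the fraction of ordered adjacencies (consecutive elements of the
#' superscaffold, bins compared by their extreme members) that contradict the
#' true order. The comparison is orientation-invariant: errors are counted
#' in the reading direction (forward or fully reversed) that fits the truth
#' best. When piece lengths and the reference length are supplied, the gap
#' percentage (reference not covered by linked pieces) is reported too.
#'
#' @param ssc a `superscaffold`.
#' @param truth data.frame `contig_id`, `order` (e.g. from
#'   [fragment_reference()]).
#' @param contig_lengths optional named lengths of the sequence contigs.
#' @param reference_length optional reference length (bp) for the gap
#'   percentage.
#' @return list `n_adjacencies`, `n_erroneous`, `error_pct`, `gap_pct`.
#' @export
evaluate_superscaffold <- function(ssc, truth, contig_lengths = NULL,
                                   reference_length = NULL) {
  ord <- stats::setNames(truth$order, truth$contig_id)
  els <- lapply(ssc$elements, function(e) unname(ord[e]))
  n_adj <- length(els) - 1L
  if (n_adj < 1L) {
    err <- 0L
  } else {
    fwd <- sum(vapply(seq_len(n_adj), function(i)
      max(els[[i]]) > min(els[[i + 1L]]), logical(1)))
    rev_ <- sum(vapply(seq_len(n_adj), function(i)
      min(els[[i]]) < max(els[[i + 1L]]), logical(1)))
    err <- min(fwd, rev_)
  }
  gap_pct <- NULL
  if (!is.null(contig_lengths) && !is.null(reference_length)) {
    members <- unlist(ssc$elements, use.names = FALSE)
    gap_pct <- 100 * (1 - sum(contig_lengths[members]) / reference_length)
  }
  list(n_adjacencies = max(n_adj, 0L), n_erroneous = err,
       error_pct = if (n_adj > 0L) 100 * err / n_adj else 0,
       gap_pct = gap_pct)
}
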