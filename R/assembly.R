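#' Construct a fingerprint set
#'
#' A fingerprint is the set of bands characterising one clone: sequence tags
#' (WGP mode, matched exactly) or integer band sizes (banded mode, matched
#' within a tolerance).
#'
#' @param bands named list, one element per clone: a character vector of tags
#'   (WGP mode) or a numeric vector of band sizes (banded mode).
#' @return a `wgp_fingerprints` object (named list; attribute `mode`).
#' @export
fingerprints <- function(bands) {
  stopifnot(is.list(bands), !is.null(names(bands)))
  modes <- vapply(bands, function(b) {
    if (is.character(b)) "wgp" else if (is.numeric(b)) "banded"
    else stop("bands must be character (tags) or numeric (sizes)",
              call. = FALSE)
  }, character(1))
  if (length(unique(modes)) > 1L) {
    stop("all fingerprints must share one mode", call. = FALSE)
  }
  bands <- lapply(bands, function(b) {
    if (is.character(b)) sort(unique(b)) else sort(b)
  })
  structure(bands, mode = modes[1] %||% "wgp", class = "wgp_fingerprints")
}

#' Fingerprints from a tag assignment or clone tag table
#'
#' @param x a `wgp_assignment` or a data.frame with `clone_id` and
#'   `tag_sequence` columns.
#' @return a `wgp_fingerprints` object in WGP mode.
#' @export
fingerprints_from_tags <- function(x) {
  if (inherits(x, "wgp_assignment")) x <- x$assignment
  stopifnot(all(c("clone_id", "tag_sequence") %in% names(x)))
  fingerprints(split(x$tag_sequence, x$clone_id))
}

#' Assembly parameters
#'
#' @param gellen virtual band space size G; the single-band coincidence
#'   probability is `(2 * tolerance + 1) / gellen`.
#' @param tolerance band-size tolerance (0 for sequence tags).
#' @param from_end a clone is an "end clone" of a contig if its placement
#'   starts within `from_end` consensus band slots of either contig end.
#' @param cutoff_schedule ordered Sulston-score cutoffs, strictly increasing
#'   (decreasing stringency); default 1e-75 stepping the exponent by +5 to
#'   1e-05 (15 steps).
#' @param dq_max_q maximum tolerated fraction of questionable (Q) clones in a
#'   contig before the DQer dissolves it.
#' @param dq_step number of schedule steps of extra stringency applied when
#'   re-assembling a dissolved contig.
#' @param match minimum shared bands required for end joins and merges.
#' @param q_window window slack multiplier for the Q-clone fit test.
#' @param q_threshold a clone is Q when less than this fraction of its bands
#'   fits a single placement window on the consensus.
#' @param q_stretch a clone is also Q when its placement interval spans more
#'   than `q_stretch` times its band count in consensus slots (its bands are
#'   scattered instead of co-located).
#' @return an `AssemblyParams` list.
#' @export
assembly_params <- function(gellen = 110000L, tolerance = 0L, from_end = 8L,
                            cutoff_schedule = 10^seq(-75, -5, by = 5),
                            dq_max_q = 0.10, dq_step = 3L, match = 1L,
                            q_window = 1.25, q_threshold = 0.5,
                            q_stretch = 3) {
  if (any(diff(cutoff_schedule) <= 0)) {
    stop("`cutoff_schedule` must be strictly increasing (less stringent)",
         call. = FALSE)
  }
  structure(list(gellen = gellen, tolerance = tolerance, from_end = from_end,
                 cutoff_schedule = cutoff_schedule, dq_max_q = dq_max_q,
                 dq_step = dq_step, match = match, q_window = q_window,
                 q_threshold = q_threshold, q_stretch = q_stretch),
            class = "AssemblyParams")
}

#' Shared-band count between two fingerprints
#'
#' WGP mode (tolerance 0): size of the exact tag-set intersection. Banded
#' mode: maximum one-to-one matching of bands within `tolerance`, computed
#' greedily on sorted bands (each band used at most once).
#'
#' @param a,b band vectors or single-clone elements of a `wgp_fingerprints`.
#' @param tolerance band-size tolerance (ignored in WGP mode).
#' @return integer count of matched bands.
#' @export
match_count <- function(a, b, tolerance = 0L) {
  if (is.character(a) != is.character(b)) {
    stop("fingerprint mode mismatch", call. = FALSE)
  }
  if (is.character(a)) return(length(intersect(a, b)))
  a <- sort(a); b <- sort(b)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= length(a) && j <= length(b)) {
    d <- a[i] - b[j]
    if (abs(d) <= tolerance) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (d < 0) i <- i + 1L else j <- j + 1L
  }
  m
}

# Upper binomial tail in log space: P(X >= M), X ~ Bin(n_hi, q) with
# q = 1 - (1 - p)^n_lo. Stays accurate for scores far below 1e-75.
sulston_tail <- function(n_lo, n_hi, M, p) {
  if (M <= 0L) return(1)
  q <- -expm1(n_lo * log1p(-p))
  if (q <= 0) return(0)
  if (q >= 1) return(1)
  k <- M:n_hi
  lt <- lchoose(n_hi, k) + k * log(q) + (n_hi - k) * log1p(-q)
  mx <- max(lt)
  min(exp(mx + log(sum(exp(lt - mx)))), 1)
}

#' Sulston coincidence score
#'
#' Probability that two non-overlapping clones share at least the observed
#' number of bands by chance. With `n_lo`/`n_hi` the smaller/larger band
#' count, `M` the shared-band count, single-band coincidence probability
#' `p = (2 * tolerance + 1) / gellen` and `q = 1 - (1 - p)^n_lo`, the score
#' is the upper tail `P(Bin(n_hi, q) >= M)`, evaluated in log space. Lower
#' scores are stronger evidence of true overlap.
#'
#' @param a,b band vectors (see [match_count()]); both non-empty.
#' @param params an [assembly_params()] list.
#' @return the coincidence probability in `[0, 1]`.
#' @export
sulston_score <- function(a, b, params = assembly_params()) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("fingerprints must be non-empty", call. = FALSE)
  }
  M <- match_count(a, b, params$tolerance)
  p <- (2 * params$tolerance + 1) / params$gellen
  sulston_tail(min(length(a), length(b)), max(length(a), length(b)), M, p)
}

# Sparse pairwise score table: only clone pairs sharing >= 1 band can have a
# score below 1, so only those are enumerated (via an inverted band index in
# WGP mode; dense enumeration in banded mode).
score_table <- function(fps, params) {
  n <- length(fps)
  sizes <- lengths(fps)
  p <- (2 * params$tolerance + 1) / params$gellen
  if (attr(fps, "mode") == "wgp") {
    dt <- data.table(band = unlist(fps, use.names = FALSE),
                     idx = rep(seq_len(n), sizes))
    pairs <- merge(dt, dt, by = "band", allow.cartesian = TRUE)[idx.x < idx.y]
    if (nrow(pairs) == 0L) {
      return(data.table(i = integer(0), j = integer(0), m = integer(0),
                        score = numeric(0)))
    }
    tab <- pairs[, .(m = .N), by = .(i = idx.x, j = idx.y)]
  } else {
    if (n < 2L) {
      return(data.table(i = integer(0), j = integer(0), m = integer(0),
                        score = numeric(0)))
    }
    cmb <- utils::combn(n, 2L)
    m <- mapply(function(i, j) match_count(fps[[i]], fps[[j]], params$tolerance),
                cmb[1L, ], cmb[2L, ])
    tab <- data.table(i = cmb[1L, ], j = cmb[2L, ], m = as.integer(m))[m > 0L]
  }
  tab[, score := mapply(function(i, j, m)
    sulston_tail(min(sizes[i], sizes[j]), max(sizes[i], sizes[j]), m, p),
    i, j, m)]
  tab[]
}

# union-find
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, x) {
  while (parent[x] != x) x <- parent[x]
  x
}
uf_union <- function(parent, a, b) {
  ra <- uf_find(parent, a); rb <- uf_find(parent, b)
  if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  parent
}
uf_components <- function(parent) {
  roots <- vapply(seq_along(parent), function(x) uf_find(parent, x), integer(1))
  split(seq_along(parent), roots)
}

#' Order the clones of one contig and build its consensus band (CB) map
#'
#' Clones are ordered by spectral seriation of the shared-band similarity
#' matrix (Fiedler vector of the graph Laplacian); consensus band slots are
#' the union of bands ordered by their mean clone rank. A clone is flagged
#' questionable (Q) when fewer than `q_threshold` of its bands fall inside a
#' single placement window on the consensus (counting only bands shared with
#' at least one other clone in the contig), or when its placement interval
#' spans more than `q_stretch` times its band count in slots, i.e. its bands
#' scatter over the consensus instead of co-locating.
#'
#' @param fps a `wgp_fingerprints` restricted to the contig's clones.
#' @param params an [assembly_params()] list.
#' @return list `clones` (ordered ids), `cb` (data.frame `band`, `slot`),
#'   `placements` (`clone_id`, `start_slot`, `end_slot`, `n_bands`, `fit`,
#'   `q`), `length_cb`, `q_clones`.
#' @export
consensus_order <- function(fps, params = assembly_params()) {
  n <- length(fps)
  stopifnot(n >= 1L)
  ids <- names(fps)
  if (n == 1L) {
    bands <- fps[[1L]]
    cb <- data.frame(band = bands, slot = seq_along(bands))
    pl <- data.frame(clone_id = ids, start_slot = 1L,
                     end_slot = length(bands), n_bands = length(bands),
                     fit = 1, q = FALSE)
    return(list(clones = ids, cb = cb, placements = pl,
                length_cb = length(bands), q_clones = character(0)))
  }
  S <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    S[i, j] <- S[j, i] <- match_count(fps[[i]], fps[[j]], params$tolerance)
  }
  L <- diag(rowSums(S)) - S
  ev <- eigen(L, symmetric = TRUE)
  fiedler <- ev$vectors[, n - 1L]
  rank <- order(order(fiedler, seq_len(n)))
  # band slot = mean rank of the clones carrying the band
  band_vec <- unlist(fps, use.names = FALSE)
  owner <- rep(seq_len(n), lengths(fps))
  pos <- tapply(rank[owner], band_vec, mean)
  bands <- names(pos)[order(pos, names(pos))]
  slot <- stats::setNames(seq_along(bands), bands)
  shared <- names(which(table(band_vec) >= 2L))
  pl <- lapply(seq_len(n), function(i) {
    b <- fps[[i]]
    s_all <- unname(slot[b])
    k <- length(b)
    s_sh <- unname(slot[intersect(b, shared)])
    w <- ceiling(params$q_window * k) + 2L
    fit <- if (length(s_sh) == 0L) 0 else {
      s_sh <- sort(s_sh)
      best <- 0L; lo <- 1L
      for (hi in seq_along(s_sh)) {
        while (s_sh[hi] - s_sh[lo] > w) lo <- lo + 1L
        best <- max(best, hi - lo + 1L)
      }
      best / k
    }
    stretch <- (max(s_all) - min(s_all) + 1L) / k
    data.frame(clone_id = ids[i], start_slot = min(s_all),
               end_slot = max(s_all), n_bands = k, fit = fit,
               q = fit < params$q_threshold || stretch > params$q_stretch)
  })
  pl <- do.call(rbind, pl)
  ord <- order(rank)
  pl <- pl[ord, , drop = FALSE]
  rownames(pl) <- NULL
  list(clones = ids[ord],
       cb = data.frame(band = bands, slot = seq_along(bands)),
       placements = pl, length_cb = length(bands),
       q_clones = pl$clone_id[pl$q])
}

make_map <- function(fps, members, params, cutoff) {
  sizes <- vapply(members, length, integer(1))
  contig_sets <- members[sizes >= 2L]
  # stable contig numbering by smallest member index
  if (length(contig_sets)) {
    contig_sets <- contig_sets[order(vapply(contig_sets, min, numeric(1)))]
  }
  contigs <- lapply(seq_along(contig_sets), function(k) {
    sub <- fps[contig_sets[[k]]]
    attr(sub, "mode") <- attr(fps, "mode")
    class(sub) <- "wgp_fingerprints"
    c(list(contig_id = sprintf("ctg_%04d", k)), consensus_order(sub, params))
  })
  singles <- names(fps)[unlist(members[sizes == 1L], use.names = FALSE)]
  structure(list(contigs = contigs, singletons = sort(singles),
                 params = params, cutoff = cutoff),
            class = "wgp_map")
}

#' @export
print.wgp_map <- function(x, ...) {
  nq <- sum(vapply(x$contigs, function(ct) length(ct$q_clones), integer(1)))
  cat(sprintf("wgp_map: %d contigs, %d singletons, %d Q clones (cutoff %.0e)\n",
              length(x$contigs), length(x$singletons), nq, x$cutoff))
  invisible(x)
}

#' Clones contained in a map (contigs + singletons)
#' @param map a `wgp_map`.
#' @return character vector of clone ids.
#' @export
map_clones <- function(map) {
  c(unlist(lapply(map$contigs, `[[`, "clones"), use.names = FALSE),
    map$singletons)
}

single_linkage_members <- function(n, st, cutoff, match) {
  parent <- uf_new(n)
  pass <- st[score <= cutoff & m >= match]
  if (nrow(pass)) {
    for (r in seq_len(nrow(pass))) {
      parent <- uf_union(parent, pass$i[r], pass$j[r])
    }
  }
  uf_components(parent)
}

#' Incremental contig build at a single cutoff
#'
#' Single-linkage clustering: the transitive closure of the relation
#' "Sulston score <= cutoff (with at least `match` shared bands)" defines the
#' contigs; clones in no passing pair remain singletons. Each contig receives
#' a consensus band map via [consensus_order()].
#'
#' @param fps a `wgp_fingerprints` object.
#' @param cutoff Sulston-score cutoff in (0, 1).
#' @param params an [assembly_params()] list.
#' @return a `wgp_map` object.
#' @export
build_contigs_incremental <- function(fps, cutoff, params = assembly_params()) {
  stopifnot(inherits(fps, "wgp_fingerprints"))
  if (cutoff <= 0 || cutoff >= 1) stop("`cutoff` must be in (0, 1)", call. = FALSE)
  st <- score_table(fps, params)
  members <- single_linkage_members(length(fps), st, cutoff, params$match)
  make_map(fps, members, params, cutoff)
}

end_clone_table <- function(map) {
  fe <- map$params$from_end
  res <- lapply(map$contigs, function(ct) {
    pl <- ct$placements
    is_end <- pl$start_slot <= fe + 1L | pl$end_slot >= ct$length_cb - fe
    data.frame(contig_id = ct$contig_id, clone_id = pl$clone_id[is_end])
  })
  do.call(rbind, res) %||%
    data.frame(contig_id = character(0), clone_id = character(0))
}

#' Stepwise stringency assembly with end merging and DQing
#'
#' Performs an initial incremental build at the first (most stringent) cutoff
#' of the schedule, then at each subsequent cutoff: (i) singleton-to-end
#' joins, where a singleton joins the contig whose end clone it matches best
#' below the cutoff; (ii) end-to-end merges of contigs whose end clones pass
#' the cutoff with at least `match` shared bands; (iii) the DQer, which
#' dissolves any contig containing more than `dq_max_q` questionable clones
#' and re-assembles its members `dq_step` schedule steps more stringently.
#' Per-step statistics (contig count, Q-clone count, map length in CB units)
#' are recorded.
#'
#' @param fps a `wgp_fingerprints` object.
#' @param params an [assembly_params()] list.
#' @return a `wgp_map` with an additional `step_stats` data.frame.
#' @export
stepwise_assembly <- function(fps, params = assembly_params()) {
  stopifnot(inherits(fps, "wgp_fingerprints"))
  sched <- params$cutoff_schedule
  n <- length(fps)
  idx <- stats::setNames(seq_len(n), names(fps))
  st <- score_table(fps, params)
  step_ratio <- if (length(sched) > 1L) sched[2] / sched[1] else 1e5
  map <- build_contigs_incremental(fps, sched[1], params)
  stats_rows <- list(step_stats_row(map, 1L, sched[1]))
  for (s in seq_along(sched)[-1]) {
    cutoff <- sched[s]
    ## (i) singleton-to-end joins
    ends <- end_clone_table(map)
    if (nrow(ends) && length(map$singletons)) {
      eidx <- idx[ends$clone_id]
      cand <- rbind(
        st[i %in% idx[map$singletons] & j %in% eidx,
           .(s_idx = i, e_idx = j, m, score)],
        st[j %in% idx[map$singletons] & i %in% eidx,
           .(s_idx = j, e_idx = i, m, score)])
      cand <- cand[score <= cutoff & m >= params$match]
      if (nrow(cand)) {
        emap <- ends
        emap$e_idx <- idx[emap$clone_id]
        cand <- merge(cand, as.data.table(emap)[, .(e_idx, contig_id)],
                      by = "e_idx", allow.cartesian = TRUE)
        setorder(cand, s_idx, score, contig_id)
        best <- cand[, .SD[1L], by = s_idx]
        joined <- names(idx)[best$s_idx]
        add <- split(joined, best$contig_id)
        for (cid in names(add)) {
          k <- which(vapply(map$contigs, `[[`, character(1), "contig_id") == cid)
          map$contigs[[k]]$clones <- c(map$contigs[[k]]$clones, add[[cid]])
        }
        map$singletons <- setdiff(map$singletons, joined)
      }
    }
    ## (ii) end-to-end merges (on membership after joins)
    member_sets <- lapply(map$contigs, function(ct) unname(idx[ct$clones]))
    groups <- c(member_sets, as.list(unname(idx[map$singletons])))
    if (length(map$contigs) >= 2L) {
      ends <- end_clone_table(map)  # end status from the pre-join consensus
      ec <- as.data.table(ends)
      ec[, e_idx := idx[clone_id]]
      ep <- merge(st[score <= cutoff & m >= params$match],
                  ec[, .(e_idx, cid_a = contig_id)],
                  by.x = "i", by.y = "e_idx")
      ep <- merge(ep, ec[, .(e_idx, cid_b = contig_id)],
                  by.x = "j", by.y = "e_idx", allow.cartesian = TRUE)
      ep <- ep[cid_a != cid_b]
      if (nrow(ep)) {
        cids <- vapply(map$contigs, `[[`, character(1), "contig_id")
        parent <- uf_new(length(groups))
        for (r in seq_len(nrow(ep))) {
          parent <- uf_union(parent, match(ep$cid_a[r], cids),
                             match(ep$cid_b[r], cids))
        }
        comp <- uf_components(parent)
        groups <- lapply(comp, function(g)
          unlist(groups[g], use.names = FALSE))
      }
    }
    map <- make_map(fps, groups, params, cutoff)
    ## (iii) DQer
    nq_before <- sum(vapply(map$contigs, function(ct)
      length(ct$q_clones), integer(1)))
    bad <- vapply(map$contigs, function(ct)
      length(ct$q_clones) / length(ct$clones) > params$dq_max_q, logical(1))
    if (any(bad)) {
      dq_cut <- cutoff * step_ratio^(-params$dq_step)
      keep_groups <- lapply(map$contigs[!bad], function(ct) unname(idx[ct$clones]))
      redone <- lapply(map$contigs[bad], function(ct) {
        sub_idx <- unname(idx[ct$clones])
        sub_st <- st[i %in% sub_idx & j %in% sub_idx]
        parent <- uf_new(length(fps))
        pass <- sub_st[score <= dq_cut & m >= params$match]
        if (nrow(pass)) for (r in seq_len(nrow(pass))) {
          parent <- uf_union(parent, pass$i[r], pass$j[r])
        }
        comp <- uf_components(parent)
        comp[vapply(comp, function(g) any(g %in% sub_idx), logical(1))]
      })
      groups <- c(keep_groups, unlist(redone, recursive = FALSE),
                  as.list(unname(idx[map$singletons])))
      map <- make_map(fps, groups, params, cutoff)
    }
    stats_rows[[s]] <- step_stats_row(map, s, cutoff, nq_before)
  }
  map$step_stats <- do.call(rbind, stats_rows)
  rownames(map$step_stats) <- NULL
  map
}

step_stats_row <- function(map, step, cutoff, nq_before = NA_integer_) {
  data.frame(
    step = step, cutoff = cutoff,
    n_contigs = length(map$contigs),
    n_singletons = length(map$singletons),
    n_q_clones = sum(vapply(map$contigs, function(ct)
      length(ct$q_clones), integer(1))),
    n_q_before_dq = nq_before,
    length_cb = sum(vapply(map$contigs, `[[`, numeric(1), "length_cb")))
}

#' Physical map length in Mb
#'
#' Sum over contigs of the consensus length in CB units times the calibrated
#' kb-per-CB unit. Singletons are excluded and reported separately.
#'
#' @param map a `wgp_map`.
#' @param cb_unit_kb kb per consensus-band unit (see [cb_unit_size()]).
#' @return list `contig_mb`, `n_singletons`.
#' @export
map_length <- function(map, cb_unit_kb) {
  stopifnot(cb_unit_kb > 0)
  cb <- sum(vapply(map$contigs, `[[`, numeric(1), "length_cb"))
  list(contig_mb = cb * cb_unit_kb / 1000,
       n_singletons = length(map$singletons))
}
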