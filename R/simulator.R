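#' Simulate a repeat-rich genome
#'
#' Builds a synthetic genome in which a configurable fraction of the sequence
#' consists of mutated copies of a small number of master transposable-element
#' (TE) families. Because copies of one family differ only by a per-copy
#' substitution rate, identical restriction-site tags can arise from distinct
#' loci, which is the repeat-confounding behaviour that drives tag loss during
#' pool deconvolution in large cereal genomes.
#'
#' @param length genome length in bp.
#' @param te_fraction requested fraction of the genome covered by TE copies
#'   (0 <= te_fraction < 1). The realised fraction is reported in the result
#'   and is always within 0.05 of the request.
#' @param n_families number of master TE families.
#' @param seed integer seed; the same seed reproduces the same genome.
#' @param family_length_range range (bp) from which each family's master
#'   length is drawn.
#' @param copy_substitution per-base substitution rate applied independently
#'   to every TE copy (default 0.02).
#' @return an object of class `wgp_genome`: a list with `sequence` (character
#'   string), `te_intervals` (data.frame with 0-based half-open `start`,
#'   `end`, `family`), and `te_fraction` (realised).
#' @examples
#' g <- simulate_genome(50000, te_fraction = 0.4, n_families = 3, seed = 1)
#' g$te_fraction
#' @export
simulate_genome <- function(length, te_fraction = 0, n_families = 5L, seed = 1L,
                            family_length_range = c(3000L, 8000L),
                            copy_substitution = 0.02) {
  if (length <= 0) stop("`length` must be positive", call. = FALSE)
  if (te_fraction < 0 || te_fraction >= 1) {
    stop("`te_fraction` must be in [0, 1)", call. = FALSE)
  }
  length <- as.integer(length)
  with_seed(seed, {
    if (te_fraction == 0) {
      return(structure(
        list(sequence = random_dna(length),
             te_intervals = data.frame(start = integer(0), end = integer(0),
                                       family = integer(0)),
             te_fraction = 0),
        class = "wgp_genome"))
    }
    masters <- vapply(seq_len(n_families), function(i) {
      random_dna(sample(family_length_range[1]:family_length_range[2], 1L))
    }, character(1))
    target_te <- round(te_fraction * length)
    # choose copies (family ids) until the target TE bp is nearly reached,
    # then trim the last copy so the realised fraction is exact
    fams <- integer(0); total <- 0L
    while (total < target_te) {
      f <- sample.int(n_families, 1L)
      fams <- c(fams, f)
      total <- total + nchar(masters[f])
    }
    copy_len <- nchar(masters)[fams]
    overshoot <- total - target_te
    copy_len[length(copy_len)] <- copy_len[length(copy_len)] - overshoot
    if (copy_len[length(copy_len)] < 50L) {  # drop a vestigial last copy
      fams <- fams[-length(fams)]
      copy_len <- copy_len[-length(copy_len)]
    }
    k <- length(fams)
    # background gaps (k + 1 of them, ends included) partition the non-TE bp
    bg_total <- length - sum(copy_len)
    w <- rexp(k + 1L)
    gaps <- floor(bg_total * w / sum(w))
    gaps[1L] <- gaps[1L] + (bg_total - sum(gaps))
    pieces <- character(2L * k + 1L)
    starts <- integer(k)
    pos <- 0L
    for (i in seq_len(k)) {
      pieces[2L * i - 1L] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      copy <- substr(masters[fams[i]], 1L, copy_len[i])
      nmut <- rbinom(1L, copy_len[i], copy_substitution)
      if (nmut > 0L) copy <- mutate_bases(copy, sample.int(copy_len[i], nmut))
      pieces[2L * i] <- copy
      starts[i] <- pos
      pos <- pos + copy_len[i]
    }
    pieces[2L * k + 1L] <- random_dna(gaps[k + 1L])
    seqstr <- paste(pieces, collapse = "")
    stopifnot(nchar(seqstr) == length)
    te <- data.frame(start = starts, end = starts + copy_len, family = fams)
    structure(list(sequence = seqstr, te_intervals = te,
                   te_fraction = sum(copy_len) / length),
              class = "wgp_genome")
  })
}

#' @export
print.wgp_genome <- function(x, ...) {
  cat(sprintf("wgp_genome: %s bp, %d TE copies (%.1f%% TE)\n",
              format(nchar(x$sequence), big.mark = ","),
              nrow(x$te_intervals), 100 * x$te_fraction))
  invisible(x)
}

genome_sequence <- function(genome) {
  if (inherits(genome, "wgp_genome")) genome$sequence else as.character(genome)
}

#' Simulate a BAC library arrayed in 384-well plates
#'
#' Clone start positions are uniform over the genome and insert sizes are
#' normal, truncated below at `min_insert`. Clones fill 384-well plates
#' (16 rows x 24 columns) in order, which fixes the well geometry used by the
#' 3-D pooling design.
#'
#' @param genome a `wgp_genome` or a plain sequence string.
#' @param n_clones number of clones.
#' @param mean_insert,sd_insert insert size distribution (bp).
#' @param seed integer seed.
#' @param min_insert lower truncation for insert sizes (bp).
#' @param clones_per_plate clones placed on each plate before the next is
#'   started (up to 384). Lowering this models partially filled pooling sets,
#'   which tunes the per-plate genome coverage that drives deconvolution
#'   losses.
#' @param scatter when `TRUE`, partial plates place clones on a deterministic
#'   scattered well pattern instead of row-major fill, so row/column/box
#'   pools are all exercised.
#' @return a `wgp_clones` data.frame: `clone_id`, `plate` (1-based), `row`
#'   (0-15), `col` (0-23), `start`, `end` (0-based half-open on the genome).
#' @export
simulate_bac_library <- function(genome, n_clones, mean_insert = 138000,
                                 sd_insert = 0.1 * mean_insert, seed = 1L,
                                 min_insert = 20000,
                                 clones_per_plate = 384L, scatter = FALSE) {
  if (n_clones < 0) stop("`n_clones` must be >= 0", call. = FALSE)
  seqstr <- genome_sequence(genome)
  L <- nchar(seqstr)
  if (mean_insert <= 0) stop("`mean_insert` must be positive", call. = FALSE)
  if (mean_insert > L) {
    stop("`mean_insert` exceeds the genome length", call. = FALSE)
  }
  if (n_clones == 0) {
    out <- data.frame(clone_id = character(0), plate = integer(0),
                      row = integer(0), col = integer(0),
                      start = integer(0), end = integer(0))
    class(out) <- c("wgp_clones", "data.frame")
    return(out)
  }
  with_seed(seed, {
    stopifnot(clones_per_plate >= 1L, clones_per_plate <= 384L)
    len <- round(rnorm(n_clones, mean_insert, sd_insert))
    len <- pmin(pmax(len, min_insert), L)
    start <- floor(runif(n_clones, 0, L - len + 1))
    i <- seq_len(n_clones) - 1L
    well <- i %% clones_per_plate
    if (scatter) well <- (well * 151L) %% 384L  # coprime stride, injective
    out <- data.frame(
      clone_id = sprintf("bac_%05d", i + 1L),
      plate = i %/% clones_per_plate + 1L,
      row = well %/% 24L,
      col = well %% 24L,
      start = as.integer(start),
      end = as.integer(start + len))
    class(out) <- c("wgp_clones", "data.frame")
    out
  })
}

#' Extract clone insert sequences
#'
#' @param genome a `wgp_genome` or sequence string.
#' @param clones a `wgp_clones` data.frame.
#' @return named character vector of insert sequences.
#' @export
clone_sequences <- function(genome, clones) {
  seqstr <- genome_sequence(genome)
  out <- substring(seqstr, clones$start + 1L, clones$end)
  names(out) <- clones$clone_id
  out
}

ECORI_SITE <- "GAATTC"
MSEI_SITE <- "TTAA"
ECORI_REMNANT <- "AATTC"

find_sites <- function(seqstr, motif) {
  m <- gregexpr(motif, seqstr, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L  # 0-based starts
}

# Tags read rightward (5'->3' on the given strand) from each EcoRI cut.
# Cut boundaries: EcoRI cuts G^AATTC (boundary at site+1), MseI cuts T^TAA
# (boundary at site+1). A fragment must be bounded by cuts on both sides
# (fragments running into the sequence end carry no second adaptor).
right_tags <- function(seqstr, tag_length, min_tag) {
  eco <- find_sites(seqstr, ECORI_SITE)
  if (length(eco) == 0L) {
    return(data.frame(tag_sequence = character(0), site_coordinate = integer(0)))
  }
  mse <- find_sites(seqstr, MSEI_SITE)
  cuts <- sort(unique(c(eco + 1L, mse + 1L)))
  start <- eco + 1L                      # 0-based first base of the fragment
  nxt <- findInterval(start, cuts) + 1L  # index of the first cut > start
  keep <- nxt <= length(cuts)
  start <- start[keep]; site <- eco[keep]
  frag_len <- cuts[nxt[keep]] - start
  ok <- frag_len >= min_tag
  if (!any(ok)) {
    return(data.frame(tag_sequence = character(0), site_coordinate = integer(0)))
  }
  start <- start[ok]; site <- site[ok]; frag_len <- frag_len[ok]
  tag_len <- pmin(tag_length, frag_len)
  data.frame(tag_sequence = substring(seqstr, start + 1L, start + tag_len),
             site_coordinate = site)
}

#' In-silico EcoRI/MseI digestion into sequence tags
#'
#' Locates all EcoRI (GAATTC) sites and emits one tag per restriction fragment
#' that has an EcoRI end, read inward from the cut. Tags include the 5-base
#' AATTC remnant, so they align directly to genomic sequence. An internal
#' EcoRI site bounded by MseI (TTAA) or EcoRI cuts on both sides yields up to
#' two tags (one per side). Fragments shorter than `min_tag` yield nothing;
#' fragments of length in `[min_tag, tag_length)` yield truncated tags.
#' Fragments running into the sequence ends are not tagged (no second adaptor).
#'
#' @param sequence a DNA string.
#' @param tag_length nominal tag length (nt).
#' @param min_tag minimum fragment length to emit a tag.
#' @return data.frame `tag_sequence`, `site_coordinate` (0-based start of the
#'   GAATTC site), `side` ("left"/"right" of the site on the input strand).
#' @examples
#' digest_and_tag(paste0(strrep("C", 40), "GAATTC", strrep("G", 40)))
#' @export
digest_and_tag <- function(sequence, tag_length = 30L, min_tag = 26L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("`sequence` must be non-empty", call. = FALSE)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  r <- right_tags(sequence, tag_length, min_tag)
  r$side <- rep("right", nrow(r))
  # left-side tags are the right-side tags of the reverse complement;
  # a site at rc-position p maps back to L - p - 6
  lrc <- right_tags(revcomp(sequence), tag_length, min_tag)
  l <- data.frame(tag_sequence = lrc$tag_sequence,
                  site_coordinate = L - lrc$site_coordinate - 6L,
                  side = rep("left", nrow(lrc)))
  out <- rbind(r, l)
  out <- out[order(out$site_coordinate, out$side), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Digest every clone insert into tags
#'
#' @param genome a `wgp_genome` or sequence string.
#' @param clones a `wgp_clones` data.frame.
#' @param tag_length,min_tag see [digest_and_tag()].
#' @return data.frame `clone_id`, `tag_sequence`, `site_coordinate` (clone
#'   offset), `genome_coordinate`, `side`.
#' @export
clone_tags <- function(genome, clones, tag_length = 30L, min_tag = 26L) {
  ins <- clone_sequences(genome, clones)
  res <- lapply(seq_along(ins), function(i) {
    d <- digest_and_tag(ins[[i]], tag_length, min_tag)
    if (nrow(d) == 0L) return(NULL)
    data.frame(clone_id = names(ins)[i], d,
               genome_coordinate = clones$start[i] + d$site_coordinate)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(clone_id = character(0), tag_sequence = character(0),
                      site_coordinate = integer(0), side = character(0),
                      genome_coordinate = integer(0))
  }
  rownames(out) <- NULL
  out
}

#' Build the 3-D row/column/split-box pooling design
#'
#' Per 384-well plate: 8 row pools of two plate rows (48 clones), 8 column
#' pools of three plate columns (48 clones), and 6 split-box pools (64 clones)
#' that differentiate the six wells of each 2x3 row-by-column block, i.e. 22
#' pools per plate. Every clone is a member of exactly one pool per dimension.
#'
#' @param clones a `wgp_clones` data.frame.
#' @return a `wgp_pools` object: data.frame `pool_id`, `plate`, `dimension`
#'   ("row"/"column"/"box"), `clone_id`.
#' @export
build_pools <- function(clones) {
  stopifnot(is.data.frame(clones))
  if (nrow(clones) == 0L) {
    out <- data.frame(pool_id = character(0), plate = integer(0),
                      dimension = character(0), clone_id = character(0))
    class(out) <- c("wgp_pools", "data.frame")
    return(out)
  }
  if (any(clones$row < 0 | clones$row > 15 | clones$col < 0 | clones$col > 23)) {
    stop("clone wells out of the 16x24 plate range", call. = FALSE)
  }
  key <- paste(clones$plate, clones$row, clones$col)
  if (anyDuplicated(key)) {
    stop("duplicate well occupancy in the clone library", call. = FALSE)
  }
  rowp <- clones$row %/% 2L
  colp <- clones$col %/% 3L
  boxp <- (clones$row %% 2L) * 3L + clones$col %% 3L
  out <- rbind(
    data.frame(pool_id = sprintf("P%02d_R%d", clones$plate, rowp + 1L),
               plate = clones$plate, dimension = "row",
               clone_id = clones$clone_id),
    data.frame(pool_id = sprintf("P%02d_C%d", clones$plate, colp + 1L),
               plate = clones$plate, dimension = "column",
               clone_id = clones$clone_id),
    data.frame(pool_id = sprintf("P%02d_B%d", clones$plate, boxp + 1L),
               plate = clones$plate, dimension = "box",
               clone_id = clones$clone_id))
  out <- out[order(out$pool_id, out$clone_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("wgp_pools", "data.frame")
  out
}

#' Default barcode set for a pool design
#'
#' Deterministically enumerates distinct `width`-nt barcodes as a base-4
#' counter over the first `width - 1` positions plus a parity base (digit sum
#' mod 4). The parity base gives the set a minimum pairwise Hamming distance
#' of 2, so a single sequencing error can never convert one valid barcode
#' into another.
#'
#' @param pool_ids character vector of pool identifiers.
#' @param width barcode length (nt).
#' @return named character vector, one barcode per pool.
#' @export
default_barcodes <- function(pool_ids, width = 6L) {
  n <- length(pool_ids)
  if (4^(width - 1L) < n) {
    stop("barcode width too small for pool count", call. = FALSE)
  }
  idx <- seq_len(n) - 1L
  bc <- vapply(idx, function(i) {
    d <- integer(width - 1L)
    for (j in seq_len(width - 1L)) { d[j] <- i %% 4L; i <- i %/% 4L }
    paste(BASES[c(d, sum(d) %% 4L) + 1L], collapse = "")
  }, character(1))
  names(bc) <- pool_ids
  bc
}

#' Simulate pooled, barcoded tag sequencing reads
#'
#' For every (pool, member clone, tag) triple, emits `depth` reads of the form
#' `barcode + tag` truncated to `read_length`; the tag itself begins with the
#' AATTC EcoRI remnant. Uniform substitution errors are applied at
#' `sub_error_rate` per base.
#'
#' @param pools a `wgp_pools` object.
#' @param tags clone tag table from [clone_tags()] (`clone_id`,
#'   `tag_sequence`).
#' @param read_length total read length (nt).
#' @param sub_error_rate per-base substitution probability.
#' @param barcode_map named character vector pool_id -> barcode; defaults to
#'   [default_barcodes()] over the pools present.
#' @param depth reads per (pool, clone, tag).
#' @param seed integer seed.
#' @return data.frame `pool_id`, `clone_id` (true provenance), `read`.
#' @export
simulate_reads <- function(pools, tags, read_length = 36L, sub_error_rate = 0,
                           barcode_map = NULL, depth = 1L, seed = 1L) {
  stopifnot(inherits(pools, "wgp_pools"))
  if (is.null(barcode_map)) {
    barcode_map <- default_barcodes(unique(pools$pool_id))
  }
  if (anyDuplicated(barcode_map)) {
    stop("barcode collision: pool barcodes must be distinct", call. = FALSE)
  }
  missing <- setdiff(unique(pools$pool_id), names(barcode_map))
  if (length(missing)) {
    stop("pools without barcode: ", paste(head(missing), collapse = ", "),
         call. = FALSE)
  }
  mem <- merge(as.data.frame(pools)[, c("pool_id", "clone_id")],
               tags[, c("clone_id", "tag_sequence")], by = "clone_id")
  if (nrow(mem) == 0L) {
    return(data.frame(pool_id = character(0), clone_id = character(0),
                      read = character(0)))
  }
  mem <- mem[rep(seq_len(nrow(mem)), each = depth), , drop = FALSE]
  read <- substr(paste0(barcode_map[mem$pool_id], mem$tag_sequence),
                 1L, read_length)
  with_seed(seed, {
    if (sub_error_rate > 0) {
      nerr <- rbinom(length(read), nchar(read), sub_error_rate)
      hit <- which(nerr > 0L)
      for (i in hit) {
        read[i] <- mutate_bases(read[i], sample.int(nchar(read[i]), nerr[i]))
      }
    }
    out <- data.frame(pool_id = mem$pool_id, clone_id = mem$clone_id,
                      read = read)
    rownames(out) <- NULL
    out
  })
}

#' Fragment a reference into draft sequence contigs with known truth
#'
#' Cuts a reference sequence into `n_pieces` contiguous, non-overlapping
#' pieces in order, withholding `gap_fraction` of the reference as
#' inter-contig gaps. The true order, orientation and coordinates are
#' recorded so that scaffolding results can be scored against truth.
#'
#' @param reference a sequence string or `wgp_genome`.
#' @param n_pieces number of contigs (>= 1).
#' @param gap_fraction fraction of the reference withheld as gaps (< 1).
#' @param seed integer seed.
#' @param min_piece minimum piece length (bp).
#' @return list with `contigs` (named character vector) and `truth`
#'   (data.frame `contig_id`, `start`, `end`, `order`, `strand`).
#' @export
fragment_reference <- function(reference, n_pieces, gap_fraction = 0,
                               seed = 1L, min_piece = 200L) {
  seqstr <- genome_sequence(reference)
  L <- nchar(seqstr)
  if (n_pieces < 1L) stop("`n_pieces` must be >= 1", call. = FALSE)
  if (gap_fraction < 0 || gap_fraction >= 1) {
    stop("`gap_fraction` must be in [0, 1)", call. = FALSE)
  }
  with_seed(seed, {
    gap_total <- round(gap_fraction * L)
    piece_total <- L - gap_total
    if (piece_total < n_pieces * min_piece) {
      stop("reference too short for the requested pieces", call. = FALSE)
    }
    w <- rexp(n_pieces)
    plen <- min_piece + floor((piece_total - n_pieces * min_piece) * w / sum(w))
    plen[1L] <- plen[1L] + (piece_total - sum(plen))
    ngap <- n_pieces - 1L
    if (ngap > 0L && gap_total > 0L) {
      wg <- rexp(ngap)
      glen <- floor(gap_total * wg / sum(wg))
      glen[1L] <- glen[1L] + (gap_total - sum(glen))
    } else {
      glen <- integer(ngap)
      # with a single piece any withheld bp trail the piece
    }
    start <- integer(n_pieces)
    pos <- 0L
    for (i in seq_len(n_pieces)) {
      start[i] <- pos
      pos <- pos + plen[i] + if (i <= ngap) glen[i] else 0L
    }
    ids <- sprintf("seqctg_%03d", seq_len(n_pieces))
    contigs <- substring(seqstr, start + 1L, start + plen)
    names(contigs) <- ids
    list(contigs = contigs,
         truth = data.frame(contig_id = ids, start = start,
                            end = start + plen,
                            order = seq_len(n_pieces), strand = "+"))
  })
}
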