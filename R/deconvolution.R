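#' @import data.table
NULL

new_assignment <- function(df) {
  df <- as.data.frame(df)[, c("tag_sequence", "clone_id")]
  df <- unique(df)
  df <- df[order(df$tag_sequence, df$clone_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(assignment = df), class = "wgp_assignment")
}

#' @export
print.wgp_assignment <- function(x, ...) {
  s <- summarize_assignment(x)
  cat(sprintf(paste0("wgp_assignment: %d tag-clone assignments, %d unique ",
                     "tags, %d BACs\n  mean tags/BAC %.1f, mean BACs/tag %.1f\n"),
              s$total_tags, s$unique_tags, s$bacs_with_tags,
              s$mean_tags_per_bac, s$mean_bacs_per_tag))
  invisible(x)
}

#' Parse barcoded tag reads
#'
#' Reads are valid only if they begin with an exact (100 percent matching) pool
#' barcode followed immediately by the exact EcoRI restriction-site remnant.
#' Invalid reads are dropped and counted. Valid reads are binned by the pool
#' their barcode identifies, with per-tag read counts.
#'
#' @param reads data.frame with a `read` column (e.g. from
#'   [simulate_reads()]).
#' @param barcode_map named character vector pool_id -> barcode.
#' @param remnant the restriction-site remnant expected after the barcode.
#' @return list with `pool_tags` (data.frame `pool_id`, `tag_sequence`
#'   including the remnant, `n_reads`) and `stats` (`total`, `valid`,
#'   `valid_fraction`).
#' @export
parse_reads <- function(reads, barcode_map, remnant = ECORI_REMNANT) {
  stopifnot(is.data.frame(reads), !is.null(names(barcode_map)))
  if (anyDuplicated(barcode_map)) {
    stop("barcode collision in `barcode_map`", call. = FALSE)
  }
  total <- nrow(reads)
  if (total == 0L) {
    return(list(pool_tags = data.frame(pool_id = character(0),
                                       tag_sequence = character(0),
                                       n_reads = integer(0)),
                stats = list(total = 0L, valid = 0L, valid_fraction = NA_real_)))
  }
  rd <- reads$read
  pool <- rep(NA_character_, total)
  for (w in sort(unique(nchar(barcode_map)))) {
    bcs <- barcode_map[nchar(barcode_map) == w]
    lut <- names(bcs)
    names(lut) <- unname(bcs)
    hit <- lut[substr(rd, 1L, w)]
    pool[is.na(pool) & !is.na(hit)] <- hit[is.na(pool) & !is.na(hit)]
  }
  bw <- nchar(barcode_map[pool])
  ok <- !is.na(pool) &
    substr(rd, bw + 1L, bw + nchar(remnant)) == remnant
  ok[is.na(ok)] <- FALSE
  tag <- substr(rd[ok], bw[ok] + 1L, nchar(rd[ok]))
  dt <- data.table(pool_id = pool[ok], tag_sequence = tag)
  pt <- dt[, .(n_reads = .N), by = .(pool_id, tag_sequence)]
  setorder(pt, pool_id, tag_sequence)
  list(pool_tags = as.data.frame(pt),
       stats = list(total = total, valid = sum(ok),
                    valid_fraction = sum(ok) / total))
}

#' Deconvolute pooled tag observations to individual BACs
#'
#' Within each plate, a tag is assigned to the well at the intersection of its
#' pools if and only if it occurs in exactly one row pool, exactly one column
#' pool and exactly one split-box pool of that plate. Tags seen in fewer than
#' three dimensions, or in several pools of the same dimension, are discarded
#' for that plate (counted, not an error). Plates are treated independently,
#' so a tag can be assigned to one BAC per plate.
#'
#' @param pool_tags data.frame `pool_id`, `tag_sequence`, optional `n_reads`
#'   (from [parse_reads()]).
#' @param pools a `wgp_pools` object.
#' @param min_reads minimum per-pool read count for a tag to count as present
#'   in that pool (suppresses sequencing-error ghost tags).
#' @return a `wgp_assignment` object; its `deconvolution` element reports
#'   per-plate tag observations assigned / ambiguous / incomplete.
#' @export
deconvolute <- function(pool_tags, pools, min_reads = 1L) {
  stopifnot(inherits(pools, "wgp_pools"))
  pt <- as.data.table(pool_tags)
  if (!"n_reads" %in% names(pt)) pt[, n_reads := 1L]
  pt <- pt[n_reads >= min_reads]
  pool_info <- unique(as.data.table(pools)[, .(pool_id, plate, dimension)])
  unknown <- setdiff(pt$pool_id, pool_info$pool_id)
  if (length(unknown)) {
    stop("pool ids absent from the pool design: ",
         paste(head(unknown), collapse = ", "), call. = FALSE)
  }
  obs <- merge(pt, pool_info, by = "pool_id")
  # per (plate, tag): number of distinct pools per dimension
  dims <- obs[, .(n_pools = uniqueN(pool_id)), by = .(plate, tag_sequence, dimension)]
  wide <- dcast(dims, plate + tag_sequence ~ dimension,
                value.var = "n_pools", fill = 0L)
  for (d in c("row", "column", "box")) {
    if (!d %in% names(wide)) wide[, (d) := 0L]
  }
  wide[, status := fifelse(row == 1L & column == 1L & box == 1L, "unique",
                    fifelse(row == 0L | column == 0L | box == 0L,
                            "incomplete", "ambiguous"))]
  keep <- wide[status == "unique", .(plate, tag_sequence)]
  # the assigned clone is the clone present in all three pools of the triple
  mem <- as.data.table(pools)[, .(pool_id, clone_id)]
  cand <- merge(merge(obs, keep, by = c("plate", "tag_sequence")),
                mem, by = "pool_id", allow.cartesian = TRUE)
  hits <- cand[, .(ndim = uniqueN(dimension)), by = .(plate, tag_sequence, clone_id)]
  assigned <- hits[ndim == 3L, .(tag_sequence, clone_id)]
  out <- new_assignment(assigned)
  out$deconvolution <- list(
    plate_tag_observations = nrow(wide),
    assigned = nrow(unique(assigned)),
    ambiguous = sum(wide$status == "ambiguous"),
    incomplete = sum(wide$status == "incomplete"))
  out
}

clone_counts <- function(assignment) {
  df <- assignment$assignment
  tab <- table(df$clone_id)
  stats::setNames(as.integer(tab), names(tab))
}

tag_counts <- function(assignment) {
  df <- assignment$assignment
  tab <- table(df$tag_sequence)
  stats::setNames(as.integer(tab), names(tab))
}

#' Tag-level quality filters
#'
#' Removes, in order: tags matching a contaminant sequence (exact substring
#' match of the tag, either strand, against the vector / host / chloroplast
#' screen set); tags containing a homopolymer run of `homopolymer` nt or
#' longer; tags present in exactly one BAC (uninformative for overlap
#' detection); tags present in more than `max_bacs` BACs (repeat-derived,
#' ambiguity-prone). The single-BAC rule is evaluated after the preceding
#' removals.
#'
#' @param assignment a `wgp_assignment`.
#' @param contaminants optional character vector of contaminant sequences.
#' @param max_bacs maximum number of BACs a tag may be assigned to.
#' @param homopolymer minimum homopolymer run length to reject.
#' @return list `assignment` (filtered), `report` (a `wgp_filter_report`).
#' @export
filter_tags <- function(assignment, contaminants = NULL, max_bacs = 12L,
                        homopolymer = 5L) {
  stopifnot(inherits(assignment, "wgp_assignment"))
  df <- assignment$assignment
  input_rows <- nrow(df)
  stages <- list()
  drop_stage <- function(df, bad_tags, stage) {
    hit <- df$tag_sequence %in% bad_tags
    stages[[stage]] <<- data.frame(stage = stage,
                                   unique_tags_removed = length(bad_tags),
                                   assignments_removed = sum(hit))
    df[!hit, , drop = FALSE]
  }
  tags <- unique(df$tag_sequence)
  if (!is.null(contaminants) && length(contaminants) > 0L) {
    hay <- paste(c(toupper(contaminants),
                   vapply(toupper(contaminants), revcomp, character(1))),
                 collapse = "#")
    bad <- tags[vapply(tags, function(t) grepl(t, hay, fixed = TRUE), logical(1))]
  } else bad <- character(0)
  df <- drop_stage(df, bad, "contaminant")
  tags <- unique(df$tag_sequence)
  df <- drop_stage(df, tags[has_homopolymer(tags, homopolymer)], "homopolymer")
  cnt <- table(df$tag_sequence)
  df <- drop_stage(df, names(cnt)[cnt == 1L], "single_bac")
  cnt <- table(df$tag_sequence)
  df <- drop_stage(df, names(cnt)[cnt > max_bacs], "over_max_bacs")
  out <- new_assignment(df)
  report <- structure(list(stages = do.call(rbind, stages),
                           input_assignments = input_rows,
                           output_assignments = nrow(out$assignment)),
                      class = "wgp_filter_report")
  list(assignment = out, report = report)
}

#' BAC-level fingerprint filters
#'
#' Removes clones whose tag counts mark them as low-quality fingerprints
#' (too few tags) or as likely chimeric / cross-contaminated clones (too many
#' tags). In relative mode the thresholds are fractions of the mean tag count
#' per BAC computed on the incoming (tag-filtered) assignment; in absolute
#' mode explicit integer cutoffs are used (remove `<= low` and `>= high`).
#'
#' @param assignment a `wgp_assignment`.
#' @param low_frac remove clones with fewer than `low_frac * mean` tags.
#' @param high_mult remove clones with more than `high_mult * mean` tags.
#' @param absolute optional `c(low, high)` integer cutoffs; when supplied,
#'   clones with `count <= low` or `count >= high` are removed instead.
#' @return list `assignment`, `report` (stages `low_tag_bac`, `high_tag_bac`).
#' @export
filter_bacs <- function(assignment, low_frac = 0.30, high_mult = 2.5,
                        absolute = NULL) {
  stopifnot(inherits(assignment, "wgp_assignment"))
  df <- assignment$assignment
  if (nrow(df) == 0L) stop("empty assignment", call. = FALSE)
  cnt <- clone_counts(assignment)
  if (is.null(absolute)) {
    m <- mean(cnt)
    low_bad <- names(cnt)[cnt < low_frac * m]
    high_bad <- names(cnt)[cnt > high_mult * m]
  } else {
    low_bad <- names(cnt)[cnt <= absolute[1]]
    high_bad <- names(cnt)[cnt >= absolute[2]]
  }
  input_rows <- nrow(df)
  n_low <- sum(df$clone_id %in% low_bad)
  df <- df[!df$clone_id %in% low_bad, , drop = FALSE]
  n_high <- sum(df$clone_id %in% high_bad)
  df <- df[!df$clone_id %in% high_bad, , drop = FALSE]
  out <- new_assignment(df)
  report <- structure(list(
    stages = data.frame(
      stage = c("low_tag_bac", "high_tag_bac"),
      clones_removed = c(length(low_bad), length(high_bad)),
      assignments_removed = c(n_low, n_high)),
    input_assignments = input_rows,
    output_assignments = nrow(out$assignment)),
    class = "wgp_filter_report")
  list(assignment = out, report = report)
}

#' @export
print.wgp_filter_report <- function(x, ...) {
  cat("wgp_filter_report:", x$input_assignments, "->",
      x$output_assignments, "assignments\n")
  print(x$stages, row.names = FALSE)
  invisible(x)
}

#' Headline ratios of a tag assignment table
#'
#' The two per-unit averages conventionally reported for a profiling run,
#' rounded to one decimal: mean tags per BAC (total assignments over BACs
#' with at least one tag) and mean BACs sharing a tag (total assignments over
#' unique tag sequences).
#'
#' @param total_tags total tag assignments.
#' @param unique_tags number of distinct tag sequences.
#' @param bacs_with_tags number of BACs with at least one assigned tag.
#' @return list `mean_tags_per_bac`, `mean_bacs_per_tag`.
#' @export
assignment_ratios <- function(total_tags, unique_tags, bacs_with_tags) {
  list(
    mean_tags_per_bac = if (bacs_with_tags > 0)
      round(total_tags / bacs_with_tags, 1) else 0,
    mean_bacs_per_tag = if (unique_tags > 0)
      round(total_tags / unique_tags, 1) else 0)
}

#' Summarize a tag assignment
#'
#' @param assignment a `wgp_assignment`.
#' @return list `total_tags`, `unique_tags`, `mean_tag_length`,
#'   `bacs_with_tags`, `mean_tags_per_bac`, `mean_bacs_per_tag` (means to one
#'   decimal).
#' @export
summarize_assignment <- function(assignment) {
  stopifnot(inherits(assignment, "wgp_assignment"))
  df <- assignment$assignment
  if (nrow(df) == 0L) {
    return(list(total_tags = 0L, unique_tags = 0L, mean_tag_length = 0,
                bacs_with_tags = 0L, mean_tags_per_bac = 0,
                mean_bacs_per_tag = 0))
  }
  total <- nrow(df)
  uniq <- length(unique(df$tag_sequence))
  nbac <- length(unique(df$clone_id))
  r <- assignment_ratios(total, uniq, nbac)
  list(total_tags = total, unique_tags = uniq,
       mean_tag_length = round(mean(nchar(df$tag_sequence)), 1),
       bacs_with_tags = nbac,
       mean_tags_per_bac = r$mean_tags_per_bac,
       mean_bacs_per_tag = r$mean_bacs_per_tag)
}
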