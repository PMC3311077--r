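#' Read a FASTA file
#'
#' Tolerates wrapped lines and CRLF line endings.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(sequences, path, width = 70L) {
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Write a TSV with versioned header comments
#'
#' @param df data.frame.
#' @param path output path.
#' @param schema short schema name written as a `#` comment.
#' @export
write_tsv <- function(df, path, schema = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(schema)) {
    writeLines(sprintf("# wgpmap schema: %s v1", schema), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

#' Read a BED file of 0-based half-open intervals
#'
#' @param path file path.
#' @return data.frame `chrom`, `start`, `end` (plus `name` when present).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  if (any(df$end <= df$start)) {
    stop("malformed BED interval (end <= start): line ",
         which(df$end <= df$start)[1L], call. = FALSE)
  }
  df
}

#' Serialise a physical map to TSV
#'
#' Writes two tables: clone placements (`contig_id`, `position`, `clone_id`,
#' `start_slot`, `end_slot`, `n_bands`, `fit`, `q`; singletons have contig_id
#' "singleton") and the consensus band map (`contig_id`, `band`, `slot`).
#'
#' @param map a `wgp_map`.
#' @param path placements TSV path.
#' @param cb_path CB-map TSV path (default `<path>.cb.tsv`).
#' @export
write_map_tsv <- function(map, path, cb_path = paste0(path, ".cb.tsv")) {
  pl <- do.call(rbind, lapply(map$contigs, function(ct) {
    d <- ct$placements
    data.frame(contig_id = ct$contig_id,
               position = seq_len(nrow(d)), d)
  }))
  if (length(map$singletons)) {
    pl <- rbind(pl, data.frame(
      contig_id = "singleton", position = NA_integer_,
      clone_id = map$singletons, start_slot = NA_integer_,
      end_slot = NA_integer_, n_bands = NA_integer_, fit = NA_real_,
      q = FALSE))
  }
  write_tsv(pl, path, schema = "physical_map")
  cb <- do.call(rbind, lapply(map$contigs, function(ct)
    data.frame(contig_id = ct$contig_id, ct$cb)))
  write_tsv(cb %||% data.frame(contig_id = character(0), band = character(0),
                               slot = integer(0)),
            cb_path, schema = "cb_map")
  invisible(path)
}

#' Rebuild a minimal physical map from its TSV serialisation
#'
#' The result carries contigs (ordered clones, placements, CB map, length)
#' and singletons; assembly parameters are not round-tripped.
#'
#' @param path placements TSV path.
#' @param cb_path CB-map TSV path.
#' @return a `wgp_map`.
#' @export
read_map_tsv <- function(path, cb_path = paste0(path, ".cb.tsv")) {
  pl <- read_tsv(path)
  cb <- read_tsv(cb_path)
  ids <- setdiff(unique(pl$contig_id), "singleton")
  contigs <- lapply(ids, function(cid) {
    d <- pl[pl$contig_id == cid, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    cbd <- cb[cb$contig_id == cid, c("band", "slot"), drop = FALSE]
    list(contig_id = cid, clones = d$clone_id,
         cb = cbd[order(cbd$slot), , drop = FALSE],
         placements = d[, c("clone_id", "start_slot", "end_slot",
                            "n_bands", "fit", "q")],
         length_cb = max(cbd$slot),
         q_clones = d$clone_id[d$q])
  })
  structure(list(contigs = contigs,
                 singletons = pl$clone_id[pl$contig_id == "singleton"],
                 params = assembly_params(), cutoff = NA_real_),
            class = "wgp_map")
}

#' Export superscaffolds as AGP v2.0
#'
#' Components are the linked sequence contigs; inter-element gaps are
#' written as unsized (type U, length 100, gap type `scaffold`, linkage
#' `yes`, evidence `map`). Members of an unordered bin are emitted
#' sequentially; their relative order within the bin is not asserted by the
#' map evidence.
#'
#' @param sscs list of `superscaffold` objects.
#' @param contig_lengths named lengths (bp) of the sequence contigs.
#' @param path output AGP path.
#' @return the validated AGP data.frame, invisibly.
#' @export
write_agp <- function(sscs, contig_lengths, path) {
  rows <- list()
  for (ssc in sscs) {
    members <- unlist(ssc$elements, use.names = FALSE)
    pos <- 0L; part <- 0L
    for (i in seq_along(members)) {
      m <- members[i]
      len <- contig_lengths[[m]]
      if (is.null(len) || is.na(len)) {
        stop("no length for component ", m, call. = FALSE)
      }
      if (i > 1L) {
        part <- part + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          object = ssc$id, object_beg = pos + 1L, object_end = pos + 100L,
          part_number = part, component_type = "U", component_id = "100",
          component_beg = "scaffold", component_end = "yes",
          orientation = "map")
        pos <- pos + 100L
      }
      part <- part + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        object = ssc$id, object_beg = pos + 1L, object_end = pos + len,
        part_number = part, component_type = "W", component_id = m,
        component_beg = "1", component_end = as.character(len),
        orientation = "+")
      pos <- pos + len
    }
  }
  agp <- do.call(rbind, rows) %||% data.frame()
  validate_agp(agp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.0", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(agp)
}

#' Validate AGP component coordinates
#'
#' Checks that parts of each object are contiguous, 1-based and that W
#' component spans match their object spans.
#'
#' @param agp AGP data.frame as built by [write_agp()].
#' @return TRUE invisibly; errors on inconsistency.
#' @export
validate_agp <- function(agp) {
  if (nrow(agp) == 0L) return(invisible(TRUE))
  for (obj in unique(agp$object)) {
    sub <- agp[agp$object == obj, , drop = FALSE]
    sub <- sub[order(sub$part_number), , drop = FALSE]
    if (sub$object_beg[1L] != 1L) stop("AGP object must start at 1")
    if (any(sub$object_end < sub$object_beg)) stop("AGP negative span")
    if (nrow(sub) > 1L &&
        any(sub$object_beg[-1L] != sub$object_end[-nrow(sub)] + 1L)) {
      stop("AGP parts not contiguous for ", obj, call. = FALSE)
    }
    w <- sub$component_type == "W"
    span_obj <- sub$object_end[w] - sub$object_beg[w] + 1L
    span_cmp <- as.integer(sub$component_end[w]) -
      as.integer(sub$component_beg[w]) + 1L
    if (any(span_obj != span_cmp)) {
      stop("AGP component span mismatch for ", obj, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Superscaffold FASTA with unsized gaps as N spacers
#'
#' @param sscs list of `superscaffold` objects.
#' @param contig_seqs named character vector of contig sequences.
#' @param gap_n number of N characters per unsized gap.
#' @return named character vector of superscaffold sequences.
#' @export
superscaffold_fasta <- function(sscs, contig_seqs, gap_n = 100L) {
  out <- vapply(sscs, function(ssc) {
    members <- unlist(ssc$elements, use.names = FALSE)
    paste(contig_seqs[members], collapse = strrep("N", gap_n))
  }, character(1))
  names(out) <- vapply(sscs, `[[`, character(1), "id")
  out
}

#' Run configuration
#'
#' Single source of truth for pipeline thresholds; serialisable to YAML with
#' a lossless round-trip.
#'
#' @param ... overrides of the defaults.
#' @return a `wgp_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    seed = 1L,
    genome = list(length = 2000000L, te_fraction = 0.0, n_families = 5L),
    library = list(n_clones = 130L, mean_insert = 138000L,
                   sd_insert = 13800L, min_insert = 20000L,
                   clones_per_plate = 384L, scatter = FALSE),
    tags = list(tag_length = 30L, min_tag = 26L),
    reads = list(read_length = 36L, sub_error_rate = 0.0, depth = 1L),
    filters = list(max_bacs = 12L, homopolymer = 5L, low_frac = 0.30,
                   high_mult = 2.5),
    assembly = list(gellen = 110000L, tolerance = 0L, from_end = 8L,
                    schedule_exponents = seq(-75L, -5L, by = 5L),
                    dq_max_q = 0.10, dq_step = 3L, match = 1L),
    scaffold = list(min_tags = 2L, min_sites = 2L, gap_n = 100L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "wgp_config")
}

#' @rdname run_config
#' @param config a `wgp_config`.
#' @param path YAML path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "wgp_config")
}

schedule_from_config <- function(cfg) {
  assembly_params(
    gellen = cfg$assembly$gellen, tolerance = cfg$assembly$tolerance,
    from_end = cfg$assembly$from_end,
    cutoff_schedule = 10^cfg$assembly$schedule_exponents,
    dq_max_q = cfg$assembly$dq_max_q, dq_step = cfg$assembly$dq_step,
    match = cfg$assembly$match)
}
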