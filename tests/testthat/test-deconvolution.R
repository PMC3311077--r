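make_assignment <- function(tags, clones) {
  wgpmap:::new_assignment(data.frame(tag_sequence = tags, clone_id = clones))
}

test_that("parse_reads enforces exact barcode and remnant matches", {
  bc <- c(p1 = "ACACAC", p2 = "GTGTGT")
  tag <- paste0("AATTC", strrep("G", 25))
  reads <- data.frame(
    pool_id = c("p1", "p2", "p1", "p1"),
    clone_id = "c1",
    read = c(paste0("ACACAC", tag),        # valid
             paste0("GTGTGT", tag),        # valid
             paste0("ACACAA", tag),        # one barcode mismatch
             paste0("ACACAC", "TATTC", strrep("G", 25))))  # bad remnant
  pr <- parse_reads(reads, bc)
  expect_equal(pr$stats$total, 4L)
  expect_equal(pr$stats$valid, 2L)
  expect_setequal(pr$pool_tags$pool_id, c("p1", "p2"))
  expect_true(all(pr$pool_tags$tag_sequence == tag))

  # read counting per pool
  reads2 <- reads[c(1, 1, 1, 2), ]
  pr2 <- parse_reads(reads2, bc)
  expect_equal(pr2$pool_tags$n_reads[pr2$pool_tags$pool_id == "p1"], 3L)
})

test_that("deconvolution assigns plate-unique tags and discards shared ones", {
  cl <- manual_plate(6, seed = 2)
  po <- build_pools(cl)
  tags <- random_tags(8, seed = 3)
  # tags 1..6 unique to one clone; tag 7 in clones 1+2; tag 8 in clones 3+4
  tg <- data.frame(
    clone_id = c(cl$clone_id, cl$clone_id[1:2], cl$clone_id[3:4]),
    tag_sequence = c(tags[1:6], tags[7], tags[7], tags[8], tags[8]))
  pt <- noiseless_pool_tags(po, tg)
  asn <- deconvolute(pt, po)
  # all six unique tags recovered, each to its true clone
  got <- asn$assignment
  expect_setequal(paste(got$tag_sequence, got$clone_id),
                  paste(tags[1:6], cl$clone_id))
  # co-plate shared tags are ambiguous in >= 1 dimension and dropped
  expect_false(any(tags[7:8] %in% got$tag_sequence))
  expect_equal(asn$deconvolution$ambiguous, 2L)
})

test_that("a tag carried on two plates is assigned once per plate", {
  cl1 <- manual_plate(3, seed = 5)
  cl2 <- manual_plate(3, seed = 6)
  cl2$plate <- 2L
  cl2$clone_id <- sub("mc", "md", cl2$clone_id)
  cl <- rbind(cl1, cl2)
  class(cl) <- c("wgp_clones", "data.frame")
  po <- build_pools(cl)
  tag <- random_tags(1, seed = 9)
  tg <- data.frame(clone_id = c(cl1$clone_id[1], cl2$clone_id[1]),
                   tag_sequence = tag)
  asn <- deconvolute(noiseless_pool_tags(po, tg), po)
  expect_setequal(asn$assignment$clone_id,
                  c(cl1$clone_id[1], cl2$clone_id[1]))
})

test_that("tags seen in fewer than three dimensions are discarded", {
  cl <- manual_plate(4, seed = 7)
  po <- build_pools(cl)
  tg <- data.frame(clone_id = cl$clone_id[1], tag_sequence = random_tags(1))
  pt <- noiseless_pool_tags(po, tg)
  pt_partial <- pt[1:2, ]  # drop one of the three pools
  asn <- deconvolute(pt_partial, po)
  expect_equal(nrow(asn$assignment), 0L)
  expect_equal(asn$deconvolution$incomplete, 1L)
})

test_that("deconvolution is sound on a noiseless simulated plate set", {
  g <- simulate_genome(2e6, te_fraction = 0, seed = 21)
  # two plates at modest per-plate coverage
  cl <- simulate_bac_library(g, 40, mean_insert = 3e4, sd_insert = 3e3,
                             seed = 22, min_insert = 1.5e4)
  cl$plate <- rep(1:2, each = 20)
  cl$row <- (c(0:19, 0:19) * 5L) %/% 24L
  cl$col <- (c(0:19, 0:19) * 5L) %% 24L
  po <- build_pools(cl)
  tg <- clone_tags(g, cl)
  asn <- deconvolute(noiseless_pool_tags(po, tg), po)
  truth <- paste(tg$clone_id, tg$tag_sequence)
  got <- paste(asn$assignment$clone_id, asn$assignment$tag_sequence)
  expect_true(all(got %in% truth))  # no false assignments
  # every tag unique to a single clone within its plate is recovered
  tgp <- merge(tg, cl[, c("clone_id", "plate")], by = "clone_id")
  per <- tapply(tgp$clone_id, paste(tgp$plate, tgp$tag_sequence),
                function(x) length(unique(x)))
  plate_unique <- sum(per == 1L)
  expect_equal(length(got), plate_unique)
})

test_that("deconvoluted fraction drops as per-plate coverage rises", {
  g <- simulate_genome(6e5, te_fraction = 0, seed = 31)
  frac <- vapply(c(6, 18, 54), function(n) {
    cl <- simulate_bac_library(g, n, mean_insert = 3e4, sd_insert = 3e3,
                               seed = 32, min_insert = 1.5e4)
    po <- build_pools(cl)
    tg <- clone_tags(g, cl)
    asn <- deconvolute(noiseless_pool_tags(po, tg), po)
    asn$deconvolution$assigned / asn$deconvolution$plate_tag_observations
  }, numeric(1))
  expect_true(all(diff(frac) < 0.02))  # monotone within sampling error
  expect_lt(frac[3], frac[1])
})

test_that("filter_tags applies the four stages in order with bookkeeping", {
  tags <- random_tags(12, seed = 41)
  tags <- unname(vapply(tags, function(t) gsub("(.)\\1{3,}", "ACGT", t),
                        character(1)))  # scrub accidental homopolymers
  homop <- paste0("ACG", strrep("T", 5), substr(tags[1], 9, 30))
  contam <- tags[2]
  single <- tags[3]
  wide <- tags[4]   # in 13 BACs
  keep <- tags[5]   # in 12 BACs (boundary)
  normal <- tags[6:8]
  df <- rbind(
    data.frame(tag_sequence = homop, clone_id = c("b1", "b2")),
    data.frame(tag_sequence = contam, clone_id = c("b1", "b2")),
    data.frame(tag_sequence = single, clone_id = "b3"),
    data.frame(tag_sequence = wide, clone_id = sprintf("w%02d", 1:13)),
    data.frame(tag_sequence = keep, clone_id = sprintf("w%02d", 1:12)),
    data.frame(tag_sequence = rep(normal, each = 2),
               clone_id = rep(c("b1", "b2"), 3)))
  asn <- wgpmap:::new_assignment(df)
  res <- filter_tags(asn, contaminants = paste0("GGGG", contam, "CCCC"))
  st <- res$report$stages
  expect_equal(st$unique_tags_removed[st$stage == "contaminant"], 1L)
  expect_equal(st$unique_tags_removed[st$stage == "homopolymer"], 1L)
  expect_equal(st$unique_tags_removed[st$stage == "single_bac"], 1L)
  expect_equal(st$unique_tags_removed[st$stage == "over_max_bacs"], 1L)
  expect_true(keep %in% res$assignment$assignment$tag_sequence)
  expect_false(wide %in% res$assignment$assignment$tag_sequence)
  # stage counts sum to input - output
  expect_equal(sum(st$assignments_removed),
               res$report$input_assignments - res$report$output_assignments)
  # idempotence
  res2 <- filter_tags(res$assignment,
                      contaminants = paste0("GGGG", contam, "CCCC"))
  expect_identical(res2$assignment$assignment, res$assignment$assignment)
})

test_that("contaminant screen matches either strand", {
  t1 <- random_tags(1, seed = 51)
  df <- data.frame(tag_sequence = t1, clone_id = c("a", "b"))
  asn <- wgpmap:::new_assignment(df)
  res <- filter_tags(asn, contaminants = revcomp(paste0("AA", t1, "TT")))
  expect_equal(nrow(res$assignment$assignment), 0L)
})

test_that("filter_bacs removes outlier fingerprints", {
  tags <- random_tags(60, seed = 61)
  # 4 clones with 16 tags, one with 4, one with 40
  df <- rbind(
    data.frame(tag_sequence = rep(tags[1:16], 4),
               clone_id = rep(sprintf("n%d", 1:4), each = 16)),
    data.frame(tag_sequence = tags[1:4], clone_id = "low"),
    data.frame(tag_sequence = c(tags[1:30], random_tags(10, seed = 62)),
               clone_id = "high"))
  asn <- wgpmap:::new_assignment(df)
  res <- filter_bacs(asn, absolute = c(4L, 40L))
  left <- unique(res$assignment$assignment$clone_id)
  expect_false(any(c("low", "high") %in% left))
  expect_setequal(left, sprintf("n%d", 1:4))
  st <- res$report$stages
  expect_equal(st$clones_removed, c(1L, 1L))

  # relative mode on a uniform library removes nothing
  uni <- wgpmap:::new_assignment(
    data.frame(tag_sequence = rep(tags[1:16], 4),
               clone_id = rep(sprintf("n%d", 1:4), each = 16)))
  res2 <- filter_bacs(uni)
  expect_equal(nrow(res2$assignment$assignment), 64L)
  expect_error(filter_bacs(wgpmap:::new_assignment(
    data.frame(tag_sequence = character(0), clone_id = character(0)))),
    "empty")
})

test_that("summarize_assignment computes per-unit means to one decimal", {
  expect_equal(summarize_assignment(wgpmap:::new_assignment(
    data.frame(tag_sequence = character(0),
               clone_id = character(0))))$total_tags, 0L)
  tags <- random_tags(7, seed = 71)
  df <- data.frame(tag_sequence = tags[c(1, 1, 2, 3, 4, 5, 6, 7)],
                   clone_id = c("a", "b", "a", "a", "b", "b", "c", "c"))
  s <- summarize_assignment(wgpmap:::new_assignment(df))
  expect_equal(s$total_tags, 8L)
  expect_equal(s$unique_tags, 7L)
  expect_equal(s$bacs_with_tags, 3L)
  expect_equal(s$mean_tags_per_bac, round(8 / 3, 1))
  expect_equal(s$mean_bacs_per_tag, round(8 / 7, 1))
})
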