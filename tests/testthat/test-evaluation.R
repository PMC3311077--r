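test_that("tag mapping is exact, strand-aware and provenance-true", {
  st <- clean_study(4e5, 20, 4e4, seed = 81)
  aln <- map_tags_to_reference(unique(st$tags$tag_sequence), st$genome)
  expect_equal(nrow(aln[aln$tag_sequence == random_tags(1, seed = 99), ]), 0L)
  # every simulated tag places at least once inside its source interval
  m <- merge(st$tags, as.data.frame(aln), by = "tag_sequence")
  m$inside <- m$position >= m$clone_id %in% st$clones$clone_id  # placeholder
  byclone <- merge(st$tags, st$clones, by = "clone_id")
  hit <- merge(byclone, as.data.frame(aln), by = "tag_sequence")
  ok <- tapply(hit$position >= hit$start - 30 & hit$position <= hit$end,
               paste(hit$clone_id, hit$tag_sequence), any)
  expect_true(all(ok))
  # left/right tags at a site carry the same site coordinate
  d <- digest_and_tag(st$genome$sequence)
  aln_d <- map_tags_to_reference(unique(d$tag_sequence), st$genome)
  both <- names(which(table(d$site_coordinate) == 2L))
  some <- as.integer(both[1:5])
  for (sc in some) {
    tags2 <- d$tag_sequence[d$site_coordinate == sc]
    sub <- aln_d[aln_d$tag_sequence %in% tags2 & aln_d$site == sc, ]
    expect_setequal(sub$strand, c("+", "-"))
  }
  # a tag and its reverse-complemented locus: same placement, other strand
  tg1 <- aln[aln$strand == "+", ][1, ]
  rcref <- revcomp(st$genome$sequence)
  aln_rc <- map_tags_to_reference(tg1$tag_sequence, c(rc = rcref))
  expect_equal(nrow(aln_rc), sum(aln$tag_sequence == tg1$tag_sequence))
  expect_true(all(aln_rc$strand[aln_rc$position ==
    nchar(rcref) - tg1$position - nchar(tg1$tag_sequence)] == "-"))
})

test_that("classify_bacs applies a strict majority threshold", {
  tags <- random_tags(10, seed = 91)
  ref <- c(refA = paste0(strrep("C", 50),
                         paste(tags[1:5], collapse = strrep("AC", 10)),
                         strrep("G", 50)))
  df <- rbind(data.frame(tag_sequence = tags[1:10], clone_id = "half"),
              data.frame(tag_sequence = tags[1:5], clone_id = "full"))
  asn <- wgpmap:::new_assignment(df)
  aln <- map_tags_to_reference(tags, ref)
  cls <- classify_bacs(asn, aln)
  expect_true(cls$matched[cls$clone_id == "full"])     # 5/5 mapped
  expect_false(cls$matched[cls$clone_id == "half"])    # exactly 50%: strict >
})

test_that("planted fusion contigs are detected at exact counts", {
  st <- clean_study(1.2e6, 60, 5e4, seed = 101)
  fps <- fingerprints_from_tags(st$tags)
  m <- build_contigs_incremental(fps, 1e-11, assembly_params())
  aln <- map_tags_to_reference(unique(st$tags$tag_sequence), st$genome)
  ch <- detect_chimeras(m, st$assignment, aln, slack_bp = 1e5)
  mis <- misassembled_fraction(m, st$assignment, aln)
  expect_equal(length(ch$chimeric), 0L)
  expect_equal(mis$pct, 0)

  # plant a fusion: weld two contigs from distant loci into one
  ords <- order(vapply(m$contigs, function(ct) length(ct$clones), integer(1)),
                decreasing = TRUE)
  stopifnot(length(ords) >= 2)
  a <- m$contigs[[ords[1]]]; b <- m$contigs[[ords[2]]]
  fused <- a
  fused$clones <- c(a$clones, b$clones)
  m2 <- m
  m2$contigs <- c(list(fused), m$contigs[-ords[1:2]])
  ch2 <- detect_chimeras(m2, st$assignment, aln, slack_bp = 1e5)
  expect_true(fused$contig_id %in% ch2$chimeric)
  expect_equal(length(ch2$chimeric), 1L)

  # rate arithmetic: chimeras per 10 Mb of reference
  expect_equal(ch2$rate_per_10mb, 1 / (1.2 / 10))
})

test_that("planted off-target BACs give exact mis-assembly percentages", {
  st <- clean_study(1e6, 36, 6e4, seed = 111)
  fps <- fingerprints_from_tags(st$tags)
  m <- build_contigs_incremental(fps, 1e-11, assembly_params())
  # replace one clone's tags with off-target sequence absent from the genome
  victim <- m$contigs[[1]]$clones[2]
  df <- st$assignment$assignment
  n_vic <- sum(df$clone_id == victim)
  df$tag_sequence[df$clone_id == victim] <- random_tags(n_vic, seed = 112)
  asn2 <- wgpmap:::new_assignment(df)
  aln <- map_tags_to_reference(unique(df$tag_sequence), st$genome)
  mis <- misassembled_fraction(m, asn2, aln)
  expect_equal(mis$n_misassembled, 1L)
  expect_equal(mis$clones, victim)
  expect_equal(mis$pct, 100 / mis$n_evaluated)
})

test_that("cb_unit_size recovers spacing and handles arithmetic cases", {
  # arithmetic: contig spanning 610 kb with 100 CB -> 6.1 kb/CB
  fake_map <- structure(list(contigs = list(list(
    contig_id = "ctg_0001", clones = "c1", length_cb = 100L)),
    singletons = character(0)), class = "wgp_map")
  tags <- random_tags(2, seed = 121)
  ref <- c(r = paste0("G", tags[1], strrep("ACT", 203330), tags[2], "G"))
  asn <- wgpmap:::new_assignment(
    data.frame(tag_sequence = tags, clone_id = "c1"))
  aln <- map_tags_to_reference(tags, ref)
  cb <- cb_unit_size(fake_map, asn, aln)
  expect_equal(cb$mean_kb, (max(aln$site) - min(aln$site)) / 1000 / 100)
  expect_equal(cb$sd_kb, 0)

  # simulation round-trip: kb/CB within 20% of the mean inter-tag spacing
  st <- clean_study(8e5, 50, 6e4, seed = 122)
  fps <- fingerprints_from_tags(st$tags)
  m <- build_contigs_incremental(fps, 1e-11, assembly_params())
  aln2 <- map_tags_to_reference(unique(st$tags$tag_sequence), st$genome)
  cb2 <- cb_unit_size(m, st$assignment, aln2)
  spacing <- (max(aln2$site) - min(aln2$site)) /
    length(unique(aln2$tag_sequence)) / 1000
  expect_lt(abs(cb2$mean_kb - spacing) / spacing, 0.2)
  expect_error(cb_unit_size(fake_map, asn,
                            map_tags_to_reference("A", c(r = "CCCC"))),
               "mapped tags")
})

test_that("C1^2/C2 scores separate clean and fused contigs", {
  tags <- random_tags(30, seed = 131)
  # clean: 4 clones all sharing tags
  clean <- wgpmap:::new_assignment(data.frame(
    tag_sequence = c(tags[1:10], tags[6:15], tags[11:20], tags[16:25]),
    clone_id = rep(sprintf("c%d", 1:4), each = 10)))
  ct_clean <- list(contig_id = "x", clones = sprintf("c%d", 1:4),
                   length_cb = 25L)
  s_clean <- chimera_score_c1c2(ct_clean, clean)

  # all pairs share: C1 = 1 -> score = 1 / C2
  allpairs <- wgpmap:::new_assignment(data.frame(
    tag_sequence = c(tags[1:5], tags[1:5]),
    clone_id = rep(c("a", "b"), each = 5)))
  ct_all <- list(contig_id = "y", clones = c("a", "b"), length_cb = 5L)
  s_all <- chimera_score_c1c2(ct_all, allpairs)
  expect_equal(s_all$c1, 1)
  expect_equal(s_all$score, 1 / s_all$c2)

  # forced merge with nothing shared: C1 = 0 -> score 0
  none <- wgpmap:::new_assignment(data.frame(
    tag_sequence = tags[1:10], clone_id = rep(c("a", "b"), each = 5)))
  ct_none <- list(contig_id = "z", clones = c("a", "b"), length_cb = 10L)
  expect_equal(chimera_score_c1c2(ct_none, none)$score, 0)

  # fused contig of equal size scores lower than the clean one
  fused <- wgpmap:::new_assignment(data.frame(
    tag_sequence = c(tags[1:10], tags[6:15], tags[21:30],
                     random_tags(10, seed = 132)),
    clone_id = rep(sprintf("f%d", 1:4), each = 10)))
  ct_fused <- list(contig_id = "w", clones = sprintf("f%d", 1:4),
                   length_cb = 25L)
  expect_lt(chimera_score_c1c2(ct_fused, fused)$score, s_clean$score)
})

test_that("tag_landscape counts are conserved and correlations behave", {
  g <- simulate_genome(3e5, te_fraction = 0.5, n_families = 4, seed = 141)
  d <- digest_and_tag(g$sequence)
  aln <- map_tags_to_reference(unique(d$tag_sequence), g)
  # disjoint tiling (window = step): window counts sum to placements in range
  tl <- tag_landscape(g, aln, g$te_intervals, window = 50000, step = 50000)
  n_win <- nrow(tl$windows)
  in_range <- sum(aln$position < n_win * 50000)
  expect_equal(sum(tl$windows$n_tags), in_range)
  expect_true(all(tl$windows$te_pct >= 0 & tl$windows$te_pct <= 100))

  # zero variance -> r = 0 with a warning
  expect_warning(
    tl0 <- tag_landscape(g, aln,
                         data.frame(start = integer(0), end = integer(0)),
                         window = 50000, step = 10000),
    "zero variance")
  expect_equal(tl0$r, 0)

  # constructed anti-correlated fixture: tags only outside TE blocks
  blocks <- data.frame(start = seq(0, 250000, by = 100000),
                       end = seq(50000, 300000, by = 100000))
  unit <- paste0(strrep("C", 20), "TTAA", strrep("AG", 18), "GAATTC",
                 strrep("GT", 18), "TTAA")
  tagged <- strrep(unit, ceiling(50000 / nchar(unit)))
  quiet <- strrep("CT", 25000)
  ref2 <- paste0(substr(quiet, 1, 50000), substr(tagged, 1, 50000),
                 substr(quiet, 1, 50000), substr(tagged, 1, 50000),
                 substr(quiet, 1, 50000), substr(tagged, 1, 50000))
  d2 <- digest_and_tag(ref2)
  aln2 <- map_tags_to_reference(unique(d2$tag_sequence), c(ref_001 = ref2))
  tl2 <- tag_landscape(ref2, aln2, blocks, window = 50000, step = 10000)
  expect_lt(tl2$r, -0.9)
  expect_error(tag_landscape(substr(ref2, 1, 100), aln2, blocks),
               "shorter")
})

test_that("inter-tag distances include site-pair zeros and tally sites", {
  st <- clean_study(3e5, 10, 4e4, seed = 151)
  d <- digest_and_tag(st$genome$sequence)
  aln <- map_tags_to_reference(unique(d$tag_sequence), st$genome)
  itd <- inter_tag_distances(aln, st$genome)
  expect_equal(itd$min, 0)  # flanking tags of one site
  expect_equal(itd$pct_sites_no_tag + itd$pct_sites_one_tag +
                 itd$pct_sites_two_tags, 100)
  expect_gt(itd$pct_sites_two_tags, 0)

  # equally spaced single tags: mean = spacing, sd = 0
  tag <- paste0("AATTC", strrep("ACGTG", 5))
  sp <- data.frame(tag_sequence = c("x", "y", "z"),
                   reference_id = "r", position = c(0, 5000, 10000),
                   strand = "+", site = c(0, 5000, 10000))
  class(sp) <- c("wgp_alignment", "data.frame")
  ref <- c(r = strrep("C", 15000))
  itd2_d <- diff(sort(sp$site))
  expect_equal(mean(itd2_d), 5000)
  expect_equal(sd(itd2_d), 0)
})

test_that("n90_l90 equals the brute-force prefix scan", {
  expect_equal(n90_l90(100, 100), list(n90 = 100, l90 = 1L, reached = TRUE))
  expect_equal(n90_l90(c(50, 30, 15, 5), 100),
               list(n90 = 15, l90 = 3L, reached = TRUE))
  expect_false(n90_l90(c(10, 10), 100)$reached)
  expect_error(n90_l90(numeric(0), 10), "empty")
  set.seed(161)
  for (i in 1:50) {
    lens <- sample(1:5000, sample(1:40, 1), replace = TRUE)
    ref <- sum(lens) * runif(1, 0.8, 1.3)
    expect_identical(n90_l90(lens, ref), brute_n90_l90(lens, ref))
  }
})

test_that("kmer_uniqueness collapses strands and spots duplications", {
  # degenerate homopolymer: its single distinct k-mer recurs, so none is
  # seen exactly once
  expect_equal(kmer_uniqueness(strrep("A", 50), 10), 0)
  s <- random_tags(1, len = 5000, seed = 171)
  expect_gt(kmer_uniqueness(s, 21), 0.99)
  # duplicated unit: every 15-mer seen at least twice
  expect_equal(kmer_uniqueness(rep(substr(s, 1, 300), 2), 15), 0)
  # a k-mer and its reverse complement are the same observation
  expect_equal(kmer_uniqueness(c(substr(s, 1, 100),
                                 revcomp(substr(s, 1, 100))), 25), 0)
  expect_error(kmer_uniqueness("ACGT", 10), "longest")
})

test_that("gap_percentage works in N-run and reference modes", {
  expect_equal(gap_percentage(scaffolds = strrep("ACGT", 100)), 0)
  expect_equal(gap_percentage(
    scaffolds = paste0(strrep("A", 450), strrep("N", 100),
                       strrep("G", 450))), 10)
  s <- random_tags(1, len = 30000, seed = 181)
  fr <- fragment_reference(s, 6, gap_fraction = 0.3, seed = 182)
  got <- gap_percentage(placements = fr$truth, reference_length = 30000)
  expect_equal(got, 30, tolerance = 0.01)
})
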