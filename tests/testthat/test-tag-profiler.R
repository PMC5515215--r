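# Degenerate-primer scanning, 33-nt tag extraction, the two literal filters
# and the abundance table.

test_that("match_degenerate resolves IUPAC degeneracies at the right offset", {
  # R in {A,G}, N in {A,C,G,T}: a concrete site placed after 4 leading bases
  read <- paste0("AAAA", "CGACAGCCATGCATCACCT", "GGG")
  expect_equal(match_degenerate(read), 5L)  # 1-based
  expect_equal(match_degenerate("TTTTTTTTTTTTTTTTTTTTTTTT"), integer(0))
  # shorter than the primer: empty, not an error
  expect_equal(match_degenerate("ACGT"), integer(0))
})

test_that("an N in the read matches only primer code N", {
  site <- "CGACAGCCATGCATCACCT"
  # N at the primer's N position (14th) still matches
  n_at_n <- paste0(substr(site, 1, 13), "N", substr(site, 15, 19))
  expect_equal(match_degenerate(n_at_n), 1L)
  # N at a fixed position does not
  n_at_fixed <- paste0("N", substr(site, 2, 19))
  expect_equal(match_degenerate(n_at_fixed), integer(0))
  # N at a degenerate R position does not
  n_at_r <- paste0(substr(site, 1, 4), "N", substr(site, 6, 19))
  expect_equal(match_degenerate(n_at_r), integer(0))
})

test_that("match_degenerate equals the exhaustive-expansion oracle", {
  withr::local_seed(42)
  for (i in 1:40) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    # plant a concrete primer instance in half the cases
    if (i %% 2 == 0) {
      inst <- oracle_match_expand(s, "NNN")  # just to vary rng stream
      pos <- sample(1:(60 - 19 + 1), 1)
      inst <- gsub("R", sample(c("A", "G"), 1),
                   gsub("N", sample(c("A", "C", "G", "T"), 1), v6_primer()))
      # gsub replaces both Rs with the same base; that is a valid instance
      substr(s, pos, pos + 18) <- inst
    }
    expect_identical(match_degenerate(s, v6_primer()),
                     oracle_match_expand(s, v6_primer()))
    # also on a shorter primer with richer degeneracy
    expect_identical(match_degenerate(s, "ARYN"),
                     oracle_match_expand(s, "ARYN"))
  }
})

test_that("extract_v6_tags takes exactly 33 nt downstream of each match", {
  site <- "CGACAGCCATGCATCACCT"
  tag <- withr::with_seed(3, random_tag())
  read_ok <- tibble::tibble(
    read_id = "r1",
    sequence = paste0(site, tag, "ACGTACGTAC")
  )
  out <- extract_v6_tags(read_ok)
  expect_equal(out$tag_sequence, tag)
  expect_equal(nchar(out$tag_sequence), 33L)

  # fewer than 33 nt downstream: nothing
  read_short <- tibble::tibble(
    read_id = "r2",
    sequence = paste0(site, substr(tag, 1, 20))
  )
  expect_equal(nrow(extract_v6_tags(read_short)), 0L)

  # two primer sites in one read yield two tag occurrences
  tag2 <- withr::with_seed(4, random_tag())
  read_two <- tibble::tibble(
    read_id = "r3",
    sequence = paste0(site, tag, site, tag2)
  )
  expect_equal(sort(extract_v6_tags(read_two)$tag_sequence),
               sort(c(tag, tag2)))
})

test_that("tag counts round-trip from error-free generated reads", {
  plans <- tibble::tibble(
    taxon_id = c("a", "b", "c"),
    tag_sequence = withr::with_seed(8, replicate(3, random_tag())),
    n_reads = c(4, 7, 3)
  )
  sim <- gen_reads(plans, seed = 21)
  support <- tag_support(extract_v6_tags(sim$reads))
  expect_equal(
    support$total_reads[match(plans$tag_sequence, support$tag_sequence)],
    plans$n_reads,
    ignore_attr = TRUE
  )
})

test_that("the two filters are applied literally", {
  make_raw <- function(...) {
    # list of read-type counts per tag
    specs <- list(...)
    purrr::imap(specs, function(counts, tag) {
      tibble::tibble(
        tag_sequence = tag,
        read_type = sprintf("%s_type%d", tag, seq_along(counts)),
        type_count = counts
      )
    }) |> dplyr::bind_rows()
  }
  raw <- make_raw(
    TAGSINGLE = 1L,             # removed: < 2 reads
    TAGDUP = c(6L, 4L),         # removed: 6/10 >= 0.5
    TAGHALF = c(5L, 5L),        # removed: exactly 0.5 counts as dominated
    TAGOK = c(1L, 1L, 1L)       # kept: max fraction 1/3
  )
  kept <- filter_tags(raw)
  expect_equal(kept$tag_sequence, "TAGOK")
  report <- filter_tags(raw, keep_all = TRUE)
  expect_match(report$reason[report$tag_sequence == "TAGSINGLE"], "covering reads")
  expect_match(report$reason[report$tag_sequence == "TAGDUP"], "50%")
  expect_match(report$reason[report$tag_sequence == "TAGHALF"], "50%")

  # idempotent on the surviving raw records and never increases counts
  raw_kept <- raw |> dplyr::semi_join(kept, by = "tag_sequence")
  again <- filter_tags(raw_kept)
  expect_equal(again, kept)
})

test_that("error-free tags with >= 3 distinct reads give perfect recall and no survivors elsewhere", {
  withr::local_seed(99)
  plans <- tibble::tibble(
    taxon_id = sprintf("t%02d", 1:12),
    tag_sequence = replicate(12, random_tag()),
    n_reads = sample(3:10, 12, replace = TRUE)
  )
  sim <- gen_reads(plans, seed = 123)
  kept <- filter_tags(extract_v6_tags(sim$reads))
  expect_setequal(kept$tag_sequence, plans$tag_sequence)
  expect_true(all(nchar(kept$tag_sequence) == 33))
  expect_true(all(sim$truth$expect_kept))
})

test_that("build_tag_table normalises per sample over the tag union", {
  per_sample <- tibble::tibble(
    sample = c("s1", "s1", "s2"),
    tag_sequence = c("X", "Y", "Z"),
    total_reads = c(4L, 6L, 5L)
  )
  tab <- build_tag_table(per_sample)
  expect_equal(nrow(tab), 6)  # 2 samples x 3 tags
  s1 <- tab[tab$sample == "s1", ]
  expect_equal(s1$rel_abundance[match(c("X", "Y", "Z"), s1$tag_sequence)],
               c(0.4, 0.6, 0))
  # rows sum to 1
  sums <- tapply(tab$rel_abundance, tab$sample, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)
})

test_that("top_n_tags ranks by mean abundance with lexicographic ties", {
  tab <- build_tag_table(tibble::tibble(
    sample = c("s1", "s1", "s1", "s2", "s2", "s2"),
    tag_sequence = rep(c("AAA", "CCC", "TTT"), 2),
    total_reads = c(7L, 2L, 1L, 7L, 1L, 2L)
  ))
  top1 <- top_n_tags(tab, 1)
  expect_setequal(unique(top1$tag_sequence), "AAA")
  # CCC and TTT tie on mean abundance: lexicographic keeps CCC
  top2 <- top_n_tags(tab, 2)
  expect_setequal(unique(top2$tag_sequence), c("AAA", "CCC"))
  expect_message(top_n_tags(tab, 50), "keeping all")
})

test_that("profiling recovers planted relative abundances exactly at zero error", {
  plans <- tibble::tibble(
    taxon_id = c("a", "b"),
    tag_sequence = withr::with_seed(13, replicate(2, random_tag())),
    n_reads = c(4L, 16L)
  )
  sim <- gen_reads(plans, seed = 31)
  tab <- profile_tags(list(s1 = sim$reads))
  expect_equal(
    tab$rel_abundance[match(plans$tag_sequence, tab$tag_sequence)],
    c(0.2, 0.8)
  )
})
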