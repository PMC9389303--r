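test_that("the worked five-spectrum cluster merges, categorizes, transfers", {
  merged <- merge_tables(table1_psms(), table1_assignment())
  expect_equal(nrow(merged), 5)
  expect_equal(unique(merged$cluster_id), 75L)
  expect_equal(sum(merged$identification_type == "direct"), 3)

  tbl <- merged |> categorize_clusters() |> transfer_identifications()
  expect_equal(unique(tbl$cluster_category), "ptm_isomeric")
  expect_equal(unique(tbl$category_letter), "f")
  transf <- tbl[tbl$identification_type == "transfer", ]
  expect_equal(sort(transf$scan_number), c(5602L, 6033L))
  expect_equal(unique(transf$sequence), "RASPSPRAA")
  expect_equal(unique(transf$transferred_sequence), "RASPSPRAA.1.p3/p5")
  expect_equal(unique(transf$proteins),
               "Serine/arginine repetitive matrix protein 1")
  # no single modified sequence is transferred in class (f)
  expect_true(all(is.na(transf$modified_sequence)))
  # direct rows untouched
  expect_equal(tbl$modified_sequence[tbl$scan_number == 5582], "RApSPSPRAA")
})

test_that("cluster categories cover the printed classes", {
  cat_of <- function(psms, ids) {
    asg <- tibble::tibble(raw_file = psms$raw_file,
                          scan_number = psms$scan_number, cluster_id = ids)
    tbl <- merge_tables(psms, asg) |> categorize_clusters()
    unique(tbl$cluster_category)
  }
  # one unidentified spectrum -> singleton
  expect_equal(cat_of(make_psms("r", 1), 1L), "singleton")
  # all identified, same sequence -> unanimous
  expect_equal(cat_of(make_psms("r", 1:3, "AAAK", "AAAK", "P1", 50), rep(1L, 3)),
               "unanimous")
  # none identified -> fully unidentified
  expect_equal(cat_of(make_psms("r", 1:3), rep(1L, 3)), "fully_unidentified")
  # two distinct unmodified sequences -> ambiguous
  psms <- dplyr::bind_rows(
    make_psms("r", 1:2, "PEPTIDEA", "PEPTIDEA", "P1", 50),
    make_psms("r", 3, "PEPTIDEB", "PEPTIDEB", "P2", 60))
  expect_equal(cat_of(psms, rep(1L, 3)), "ambiguous")
  # one modified sequence + unidentified members -> transferable
  psms <- dplyr::bind_rows(
    make_psms("r", 1:2, "AAAK", "AAAK", "P1", 50),
    make_psms("r", 3))
  expect_equal(cat_of(psms, rep(1L, 3)), "transferable")
  # site variants + unidentified members -> PTM-isomeric
  psms <- dplyr::bind_rows(
    make_psms("r", 1, "ASASK", "ApSASK", "P1", 50),
    make_psms("r", 2, "ASASK", "ASApSK", "P1", 55),
    make_psms("r", 3))
  expect_equal(cat_of(psms, rep(1L, 3)), "ptm_isomeric")
  # differing modification counts demote to ambiguous unless disabled
  psms <- dplyr::bind_rows(
    make_psms("r", 1, "ASASK", "ApSASK", "P1", 50),
    make_psms("r", 2, "ASASK", "ApSApSK", "P1", 55),
    make_psms("r", 3))
  expect_equal(cat_of(psms, rep(1L, 3)), "ambiguous")
  asg <- tibble::tibble(raw_file = psms$raw_file,
                        scan_number = psms$scan_number, cluster_id = 1L)
  relaxed <- merge_tables(psms, asg) |>
    categorize_clusters(require_equal_mod_counts = FALSE)
  expect_equal(unique(relaxed$cluster_category), "ptm_isomeric")
  # fully identified site variants have no acceptors: unanimous + flag
  psms <- dplyr::bind_rows(
    make_psms("r", 1, "ASASK", "ApSASK", "P1", 50),
    make_psms("r", 2, "ASASK", "ASApSK", "P1", 55))
  asg <- tibble::tibble(raw_file = psms$raw_file,
                        scan_number = psms$scan_number, cluster_id = 1L)
  tbl <- merge_tables(psms, asg) |> categorize_clusters()
  expect_equal(unique(tbl$cluster_category), "unanimous")
  expect_true(all(tbl$ptm_variants))
})

test_that("merging conserves scans and invents singletons when needed", {
  psms <- make_psms("r", 1:4, c("AAAK", "AAAK", NA, NA),
                    c("AAAK", "AAAK", NA, NA), c("P1", "P1", NA, NA),
                    c(50, 60, NA, NA))
  asg <- tibble::tibble(raw_file = "r", scan_number = 1:3, cluster_id = c(1L, 1L, 1L))
  merged <- merge_tables(psms, asg)
  expect_equal(nrow(merged), 4) # conservation
  expect_false(merged$cluster_id[4] %in% merged$cluster_id[1:3])
  # a PSM scan absent from all_scans is warned about but kept
  expect_warning(
    m2 <- merge_tables(psms, asg,
                       all_scans = tibble::tibble(raw_file = "r",
                                                  scan_number = 1:3)),
    "authoritative")
  expect_equal(nrow(m2), 4)
})

test_that("decoy identifications never donate", {
  psms <- make_psms("r", 1:2, c("AAAK", NA), c("AAAK", NA), c("REV__P1", NA),
                    c(99, NA))
  psms$is_decoy <- c(TRUE, FALSE)
  asg <- tibble::tibble(raw_file = "r", scan_number = 1:2, cluster_id = 1L)
  tbl <- merge_tables(psms, asg) |> categorize_clusters() |>
    transfer_identifications()
  expect_equal(sum(tbl$identification_type == "transfer"), 0)
  expect_equal(unique(tbl$cluster_category), "fully_unidentified")
})

test_that("transfer bookkeeping: donors, acceptors and counts", {
  psms <- dplyr::bind_rows(
    make_psms("r", 1, "AAAK", "AAAK", "P1;P9", 70),
    make_psms("r", 2:4))
  asg <- tibble::tibble(raw_file = "r", scan_number = 1:4, cluster_id = 1L)
  tbl <- merge_tables(psms, asg) |> categorize_clusters() |>
    transfer_identifications()
  expect_equal(sum(tbl$identification_type == "transfer"), 3)
  expect_equal(sum(tbl$is_identified), 4)
  expect_equal(unique(tbl$proteins), "P1;P9") # copied from the donor
  # unanimous cluster: zero transfers
  psms2 <- make_psms("r", 1:3, "AAAK", "AAAK", "P1", 50)
  asg2 <- tibble::tibble(raw_file = "r", scan_number = 1:3, cluster_id = 1L)
  tbl2 <- merge_tables(psms2, asg2) |> categorize_clusters() |>
    transfer_identifications()
  expect_equal(sum(tbl2$identification_type == "transfer"), 0)
})

test_that("transfer soundness properties hold on randomized tables", {
  forbidden <- c("singleton", "unanimous", "fully_unidentified", "ambiguous")
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    seq_pool <- c("ASASK", "CCCK", "DDDK", "EEEK")
    identified <- runif(n) < 0.6
    seqs <- ifelse(identified, sample(seq_pool, n, replace = TRUE), NA)
    mods <- ifelse(!is.na(seqs) & seqs == "ASASK" & runif(n) < 0.5,
                   "ApSASK", seqs)
    psms <- make_psms(sample(c("r1", "r2"), n, replace = TRUE), 1:n,
                      seqs, mods,
                      ifelse(identified, "P1", NA),
                      ifelse(identified, round(runif(n, 40, 150)), NA))
    asg <- tibble::tibble(raw_file = psms$raw_file,
                          scan_number = psms$scan_number,
                          cluster_id = sample(1:20, n, replace = TRUE))
    tbl <- merge_tables(psms, asg) |> categorize_clusters() |>
      transfer_identifications()
    # category partition: every cluster exactly one category
    per_cl <- tapply(tbl$cluster_category, tbl$cluster_id,
                     dplyr::n_distinct)
    expect_true(all(per_cl == 1))
    cc <- category_counts(tbl)
    expect_equal(sum(cc$n_clusters), dplyr::n_distinct(tbl$cluster_id))
    # no transfer in forbidden categories
    expect_equal(sum(tbl$identification_type == "transfer" &
                       tbl$cluster_category %in% forbidden), 0)
    # transfers only in e/f clusters
    expect_true(all(tbl$cluster_category[tbl$identification_type == "transfer"]
                    %in% c("transferable", "ptm_isomeric")))
    # the multiset of direct identifications is unchanged
    before <- merge_tables(psms, asg)
    expect_equal(
      sort(paste(before$raw_file, before$scan_number,
                 before$sequence)[before$identification_type == "direct"]),
      sort(paste(tbl$raw_file, tbl$scan_number,
                 tbl$sequence)[tbl$identification_type == "direct"]))
    # idempotence
    again <- transfer_identifications(tbl)
    expect_equal(tibble::as_tibble(again), tibble::as_tibble(tbl))
  }
})

test_that("summaries count PSM gains per batch", {
  psms <- dplyr::bind_rows(
    make_psms("b1", 1:10, "AAAK", "AAAK", "P1", 50),
    make_psms("b1", 11:14))
  asg <- tibble::tibble(raw_file = "b1", scan_number = 1:14, cluster_id = 1L)
  tbl <- merge_tables(psms, asg) |> categorize_clusters() |>
    transfer_identifications()
  s <- summarize_transfers(tbl)
  row <- s[s$batch_id == "b1", ]
  expect_equal(row$n_direct, 10)
  expect_equal(row$n_transferred, 4)
  expect_equal(row$psm_gain_percent, 40)
  # empty table -> zero totals
  s0 <- summarize_transfers(tbl[0, ])
  expect_equal(s0$n_scans[s0$batch_id == "(all)"], 0)
  expect_equal(s0$n_direct[s0$batch_id == "(all)"], 0)
})
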