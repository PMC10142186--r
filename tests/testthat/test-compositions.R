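venom_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "species,record_id,source,method,toxin_family,percent_abundance"
  writeLines(c(header, rows), path)
  path
}

test_that("venom reader builds one profile per record and keeps raw totals", {
  p <- venom_csv(c(
    "Naja naja,r1,smith2020,proteome,3FTx,60",
    "Naja naja,r1,smith2020,proteome,PLA2,30",
    "Naja naja,r1,smith2020,proteome,SVMP,10"))
  prof <- read_venom_profiles(p)
  expect_length(prof, 1)
  expect_equal(prof[[1]]$raw_total_percent, 100.0)
  expect_equal(sort(names(prof[[1]]$components)), c("3FTx", "PLA2", "SVMP"))
  expect_false(prof[[1]]$normalized)
})

test_that("venom reader validates format, signs, and duplicates", {
  expect_error(read_venom_profiles(venom_csv(
    "Naja naja,r1,s,proteome,3FTx,-5")), "negative")
  expect_error(read_venom_profiles(venom_csv(c(
    "Naja naja,r1,s,proteome,3FTx,50",
    "Naja naja,r1,s,proteome,3FTx,50"))), "duplicate")
  # missing column
  p <- tempfile(fileext = ".csv")
  writeLines("species,record_id,source,method,percent_abundance", p)
  expect_error(read_venom_profiles(p), "missing column")
  # empty file with header -> empty list
  expect_length(read_venom_profiles(venom_csv(character(0))), 0)
})

test_that("tab-separated input parses identically", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("species\trecord_id\tsource\tmethod\ttoxin_family\tpercent_abundance",
               "Naja naja\tr1\ts\tproteome\t3FTx\t70",
               "Naja naja\tr1\ts\tproteome\tPLA2\t30"), p)
  prof <- read_venom_profiles(p)
  expect_equal(prof[[1]]$raw_total_percent, 100)
})

test_that("cleaning removes implausible totals and renormalizes survivors", {
  mk <- function(id, ...) abundance_profile("sp", id, "s", "proteome", c(...))
  profs <- list(mk("hi", a = 60, b = 55),          # 115 -> removed
                mk("ok", a = 60, b = 40),          # 100 -> kept, unchanged
                mk("round", a = 52.1, b = 52.1),   # 104.2 -> kept, 0.5/0.5
                mk("lo", a = 40, b = 20))          # 60  -> removed
  out <- clean_venom_profiles(profs)
  ids <- vapply(out$profiles, function(p) p$record_id, "")
  expect_setequal(ids, c("ok", "round"))
  expect_equal(out$report$n_input, 4L)
  expect_equal(out$report$n_removed_abundance, 2L)
  expect_equal(out$report$removed_ids$reason[out$report$removed_ids$id == "hi"],
               "total_above_cap")
  expect_equal(out$report$removed_ids$reason[out$report$removed_ids$id == "lo"],
               "total_below_floor")
  round_p <- out$profiles[[which(ids == "round")]]
  expect_equal(unname(round_p$components), c(0.5, 0.5))
  ok_p <- out$profiles[[which(ids == "ok")]]
  expect_equal(unname(ok_p$components), c(0.6, 0.4))
  # ratio preservation under renormalization
  expect_equal(round_p$components[["a"]] / round_p$components[["b"]],
               52.1 / 52.1, tolerance = 1e-12)
})

test_that("cleaning boundary totals follow the cap and floor exactly", {
  mk <- function(total) abundance_profile(
    "sp", paste0("t", total), "s", "proteome", c(a = total / 2, b = total / 2))
  profs <- lapply(c(89.9, 90, 100, 110, 110.1), mk)
  out <- clean_venom_profiles(profs)
  kept <- vapply(out$profiles, function(p) p$record_id, "")
  expect_setequal(kept, c("t90", "t100", "t110"))
})

test_that("cleaning and diet filtering are idempotent", {
  mk <- function(id, tot) abundance_profile("sp", id, "s", "proteome",
                                            c(a = tot * 0.6, b = tot * 0.4))
  profs <- list(mk("a", 100), mk("b", 120), mk("c", 95))
  once <- clean_venom_profiles(profs)
  twice <- clean_venom_profiles(once$profiles)
  expect_equal(lapply(twice$profiles, `[[`, "components"),
               lapply(once$profiles, `[[`, "components"))
  expect_equal(twice$report$n_removed_abundance, 0L)

  recs <- data.frame(species = c("s1", "s1", "s2"),
                     prey_family = c("Muridae", "Soricidae", "Muridae"),
                     prey_order = c("Rodentia", "Eulipotyphla", "Rodentia"),
                     n_records = c(3L, 3L, 2L))
  t1 <- filter_diet(aggregate_diet(recs, "family"))
  t2 <- filter_diet(t1$tables)
  expect_equal(t2$tables, t1$tables)
})

test_that("diet aggregation sums duplicates per level and splits species", {
  recs <- data.frame(
    species = c("sp1", "sp1", "sp2"),
    prey_family = c("Muridae", "Muridae", "Colubridae"),
    prey_order = c("Rodentia", "Rodentia", "Squamata"),
    n_records = c(3L, 2L, 4L))
  fam <- aggregate_diet(recs, "family")
  expect_length(fam, 2)
  expect_equal(fam[[1]]$counts, c(Muridae = 5L))
  expect_equal(fam[[1]]$total_records, 5L)
  ord <- aggregate_diet(recs, "order")
  expect_equal(ord[[1]]$counts, c(Rodentia = 5L))
  expect_error(aggregate_diet(transform(recs, n_records = c(0L, 2L, 4L))),
               "positive")
  # rows lacking the level label are dropped and counted
  recs$prey_family[3] <- NA
  fam2 <- aggregate_diet(recs, "family")
  expect_length(fam2, 1)
  expect_equal(attr(fam2, "n_missing_label"), 1L)
})

test_that("diet filter keeps species at exactly the minimum record count", {
  mk <- function(sp, n) structure(
    list(species = sp, level = "family",
         counts = stats::setNames(as.integer(n), "Muridae"),
         total_records = as.integer(n)),
    class = "diet_count_table")
  out <- filter_diet(list(mk("few", 4), mk("enough", 5)))
  expect_equal(vapply(out$tables, `[[`, "", "species"), "enough")
  expect_equal(out$report$removed_ids$id, "few")
  empty <- filter_diet(list())
  expect_length(empty$tables, 0)
  expect_equal(empty$report$n_input, 0L)
})

test_that("diversity table replicates species diet values across records", {
  profs <- list(
    abundance_profile("sp1", "r1", "s1", "proteome", c(a = 0.5, b = 0.5)),
    abundance_profile("sp1", "r2", "s2", "transcriptome", c(a = 0.9, b = 0.1)),
    abundance_profile("sp2", "r3", "s3", "proteome", c(a = 1)),
    abundance_profile("sp3", "r4", "s4", "proteome", c(a = 0.3, b = 0.7)))
  recs <- data.frame(species = c("sp1", "sp1", "sp2"),
                     prey_family = c("Muridae", "Soricidae", "Muridae"),
                     prey_order = c("Rodentia", NA, "Rodentia"),
                     n_records = c(6L, 4L, 7L))
  fam <- aggregate_diet(recs, "family")
  ord <- aggregate_diet(recs, "order")
  div <- diversity_table(profs, fam, ord)
  # sp3 has venom but no diet: dropped and reported
  expect_false("sp3" %in% div$species)
  expect_equal(attr(div, "dropped_species"), "sp3")
  # both sp1 records carry the same species-level diet diversity
  sp1 <- div[div$species == "sp1", ]
  expect_equal(nrow(sp1), 2)
  expect_equal(sp1$diet_shannon_family[1], sp1$diet_shannon_family[2])
  expect_equal(sp1$diet_shannon_family[1], shannon_index(c(6, 4) / 10))
  # sp1 order-level diet lost its only labelled Soricidae row -> single taxon
  expect_equal(sp1$diet_shannon_order[1], 0)
  # venom indices are per record
  expect_equal(sp1$venom_shannon[1], log(2))
  expect_equal(div$venom_simpson[div$record_id == "r3"], 0)
})

test_that("prey taxon counts tally distinct families and orders", {
  recs <- data.frame(prey_family = c("A", "B", "C", "B"),
                     prey_order = c("X", "X", "Y", "X"))
  expect_equal(count_prey_taxa(recs), c(n_families = 3L, n_orders = 2L))
  expect_equal(count_prey_taxa(recs[0, ]), c(n_families = 0L, n_orders = 0L))
  # a diet spanning 11 families in 9 orders (several orders with 2 families)
  toy <- data.frame(
    prey_family = paste0("fam", 1:11),
    prey_order = paste0("ord", c(1, 1, 2, 2, 3, 4, 5, 6, 7, 8, 9)))
  expect_equal(count_prey_taxa(toy), c(n_families = 11L, n_orders = 9L))
})
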