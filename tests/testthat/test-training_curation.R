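test_that("packaged curated tables load with the documented composition", {
  hum <- load_training_table(
    system.file("extdata", "FA_MannuallyCurated_Train.synthetic.tsv",
                package = "fabpocket"))
  expect_equal(attr(hum, "n_records"), 340)
  expect_true(all(hum$label == 1))
  expect_equal(attr(hum, "n_distinct_species"), 1)
  asp <- load_training_table(
    system.file("extdata", "FA_AllSpecie_Train.synthetic.tsv",
                package = "fabpocket"))
  expect_equal(attr(asp, "n_records"), 70)
  expect_equal(attr(asp, "n_distinct_species"), 52)
  expect_true(all(grepl("^[0-9][A-Z0-9]{3}$", c(hum$pdb_id, asp$pdb_id))))
})

test_that("duplicates collapse, bad ids are skipped, bad columns error", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("pdb_id\tchain\tligand_code\tspecies\tlabel",
               "1abc\tA\tplm\tHomo sapiens\t1",
               "1ABC\tA\tPLM\tHomo sapiens\t1",
               "2XYZ\tB\tMYR\tMus musculus\t1"), f)
  expect_warning(rec <- load_training_table(f), "duplicate")
  expect_equal(nrow(rec), 2)
  expect_equal(rec$pdb_id, c("1ABC", "2XYZ"))
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("pdb_id\tchain\tligand_code\tspecies\tlabel",
               "NOT_AN_ID\tA\tPLM\tx\t1",
               "3DEF\tA\tOLA\ty\t1"), f2)
  expect_message(rec2 <- load_training_table(f2), "malformed")
  expect_equal(rec2$pdb_id, "3DEF")
  f3 <- tempfile(fileext = ".tsv")
  writeLines(c("id\tchain", "1ABC\tA"), f3)
  expect_error(load_training_table(f3), "pdb_id")
})

test_that("ligand exclusion lists load and apply completely", {
  lst <- load_ligand_exclusion(
    system.file("extdata", "LigandTableFA.synthetic.txt",
                package = "fabpocket"))
  expect_true(all(c("PLM", "MYR", "OLA") %in% lst))
  entries <- data.frame(
    id = c("a", "b", "c"), path = "x.pdb",
    ligand_codes = c("PLM", "PLM;HEM", "NAD"), stringsAsFactors = FALSE)
  pool <- build_negative_pool(entries, lst)
  # entries bound only by excluded ligands are dropped entirely
  expect_equal(pool$id, c("b", "c"))
  expect_false(any(unlist(strsplit(pool$ligand_codes, ";")) %in% lst))
})

test_that("pocket labels follow the sphere-ligand contact rule", {
  cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = 7,
                              ligand = acyl_ligand(8)))
  lig <- cage$atoms[cage$atoms$kind == "ligand", ]
  expect_equal(nrow(lig), 8)
  expect_true(all(sqrt(lig$x^2 + lig$y^2 + lig$z^2) <
                    attr(cage, "spec")$cavity_radius))
  pockets <- detect_pockets(cage)   # ligand excluded from detection input
  lab <- label_pockets(pockets, lig)
  # oracle: explicit distance matrix per pocket
  want <- vapply(pockets, function(p) {
    hits <- 0
    for (i in seq_len(nrow(p$spheres))) {
      d <- sqrt((lig$x - p$spheres$cx[i])^2 + (lig$y - p$spheres$cy[i])^2 +
                  (lig$z - p$spheres$cz[i])^2)
      if (min(d) <= 3) hits <- hits + 1
    }
    as.integer(hits >= 3)
  }, integer(1))
  expect_equal(lab, want)
  # the cavity pocket (centroid at the origin) is the positive one
  cavity <- which.min(vapply(pockets, function(p) sum(p$centroid^2),
                             numeric(1)))
  expect_equal(lab[cavity], 1L)
  # zero-distance contact with a 1-sphere threshold
  p1 <- pockets[[1]]
  coincident <- data.frame(x = p1$spheres$cx[1], y = p1$spheres$cy[1],
                           z = p1$spheres$cz[1])
  expect_equal(label_pockets(list(p1), coincident, min_contact_spheres = 1),
               1L)
  # a far-away ligand labels nothing
  far <- data.frame(x = 100, y = 100, z = 100)
  expect_equal(label_pockets(pockets, far), rep(0L, length(pockets)))
  expect_error(label_pockets(pockets, far[0, ]), "heavy atoms")
})

test_that("build_dataset assembles labeled rows with full provenance", {
  dir <- tempfile("structs_"); dir.create(dir)
  specs <- list(
    list(id = "1AAA", lig = "SAC", spec = cage_spec(150, seed = 31,
                                                    ligand = acyl_ligand(8))),
    list(id = "2BBB", lig = "SAC", spec = cage_spec(150, seed = 32,
                                                    ligand = acyl_ligand(8))),
    list(id = "3CCC", lig = "", spec = cage_spec(150, seed = 33)),
    list(id = "4DDD", lig = "", spec = cage_spec(150, seed = 34)))
  for (sp in specs)
    write_structure_pdb(make_cage(sp$spec),
                        file.path(dir, paste0(sp$id, ".pdb")))
  records <- data.frame(
    pdb_id = c("1AAA", "2BBB", "3CCC", "4DDD", "5EEE", "6FFF"),
    chain = "*",
    ligand_code = c("SAC", "SAC", "", "", "SAC", "SAC"),
    species = "synthetic", label = c(1L, 1L, 0L, 0L, 1L, 1L),
    stringsAsFactors = FALSE)
  # 6FFF exists but lacks its ligand; 5EEE is missing entirely
  write_structure_pdb(make_cage(cage_spec(150, seed = 35)),
                      file.path(dir, "6FFF.pdb"))
  ds <- build_dataset(records, dir)
  expect_gte(nrow(ds$X), 4)
  expect_setequal(unique(ds$y), c(0L, 1L))
  expect_equal(nrow(ds$provenance), nrow(ds$X))
  expect_equal(ds$provenance$label, ds$y)
  expect_setequal(ds$skipped$pdb_id, c("5EEE", "6FFF"))
  expect_match(ds$skipped$reason[ds$skipped$pdb_id == "5EEE"], "missing")
  expect_match(ds$skipped$reason[ds$skipped$pdb_id == "6FFF"], "absent")
  # positives contribute only contact pockets; negatives contribute all
  expect_true(all(ds$provenance$label[ds$provenance$pdb_id %in%
                                        c("1AAA", "2BBB")] == 1))
  expect_true(all(ds$provenance$label[ds$provenance$pdb_id %in%
                                        c("3CCC", "4DDD")] == 0))
  # determinism: a second run reproduces the matrix exactly
  ds2 <- build_dataset(records, dir)
  expect_identical(ds$X, ds2$X)
  expect_identical(ds$y, ds2$y)
})

test_that("removing the ligand never shrinks the cavity pocket", {
  cage <- make_cage(cage_spec(n_shell_atoms = 150, seed = 7,
                              ligand = acyl_ligand(8)))
  apo <- detect_pockets(cage, include_ligands = FALSE)
  holo <- detect_pockets(cage, include_ligands = TRUE)
  nearest <- function(pk) pk[[which.min(vapply(pk, function(p)
    sum(p$centroid^2), numeric(1)))]]
  n_apo <- nearest(apo)$n_spheres
  n_holo <- if (length(holo)) {
    cand <- nearest(holo)
    if (sum(cand$centroid^2) < 4) cand$n_spheres else 0L
  } else 0L
  expect_gte(n_apo, n_holo)
})
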