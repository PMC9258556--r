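# Germplasm registry: creation, synonyms, renames, deletion policy, roles.

test_that("bulk accession creation partitions input into created and rejected", {
  st <- create_store()
  r <- add_accessions(st, data.frame(
    name = c("TX303", "TMS30572"),
    species = c("Zea mays", "Manihot esculenta")))
  expect_equal(r$created$name, c("TX303", "TMS30572"))
  expect_equal(nrow(r$rejected), 0)

  r2 <- add_accessions(st, data.frame(
    name = c("TX303", "Tx 303", "NEWONE", "GHOSTSP", "NEWONE2", "NEWONE2"),
    species = c("Zea mays", "Zea mays", "Zea mays", "No such species",
                "Zea mays", "Zea mays")))
  expect_equal(r2$created$name, c("NEWONE", "NEWONE2"))
  expect_equal(r2$rejected$name, c("TX303", "Tx 303", "GHOSTSP", "NEWONE2"))
  expect_equal(r2$rejected$reason,
               c("duplicate_name", "duplicate_name", "unknown_species",
                 "duplicate_name"))
  # partition is exact
  expect_equal(nrow(r2$created) + nrow(r2$rejected), 6)
})

test_that("synonyms resolve, collide globally, and the canonical pair works", {
  st <- demo_store()
  expect_equal(find_accession(st, "Tx 303")$name, "TX303")
  expect_true("Tx 303" %in% accession_synonyms(st, "TX303"))
  # a synonym owned by another accession is rejected
  expect_error(add_synonym(st, "TX303", "TMS30572"), class = "bb_duplicate_synonym")
  expect_error(add_synonym(st, "GHOST", "x"), class = "bb_unknown_accession")
  # adding nothing warns and is a no-op
  expect_warning(add_synonym(st, "TX303", "TX303"))
  expect_warning(add_synonym(st, "TX303", "Tx 303"))
  # a new accession colliding with a synonym is rejected
  r <- add_accessions(st, data.frame(name = "TX-303", species = "Zea mays"))
  expect_equal(r$rejected$reason, "duplicate_name")
})

test_that("rename preserves identity and all links", {
  st <- demo_store()
  add_trait_variable(st, "CO_000:0000001", "toy", scale_class = "numeric")
  lay <- new_test_layout(c("TX303", "TMS30572"), 2)
  create_trial(st, "T1", "IITA", "Mokwa", 2020, lay)
  id_before <- find_accession(st, "TX303")$id
  plots_before <- sort(st$units$name[st$units$accession_id == id_before])

  rename_accession(st, "TX303", "TX303-ELITE")
  acc <- find_accession(st, "TX303-ELITE")
  expect_equal(acc$id, id_before)
  expect_equal(sort(st$units$name[st$units$accession_id == acc$id]), plots_before)
  expect_null(find_accession(st, "TX303XYZ"))
  # renaming onto another accession's name or synonym fails
  expect_error(rename_accession(st, "TX303-ELITE", "TMS30572"),
               class = "bb_duplicate_name")
  # rename back restores the original state
  rename_accession(st, "TX303-ELITE", "TX303")
  expect_equal(find_accession(st, "TX303")$id, id_before)
})

test_that("deletion is refused while dependent objects exist", {
  st <- demo_store()
  lay <- new_test_layout(c("TX303", "TMS30572"), 2)
  create_trial(st, "T1", "IITA", "Mokwa", 2020, lay)
  expect_error(delete_accession(st, "TX303"), class = "bb_referenced")
  # an unreferenced accession deletes cleanly
  delete_accession(st, "TMEB419")
  expect_null(find_accession(st, "TMEB419"))
})

test_that("global uniqueness survives random operation sequences", {
  set.seed(99)
  st <- create_store()
  add_accessions(st, data.frame(name = sprintf("BASE%02d", 1:10),
                                species = "Zea mays"))
  for (i in 1:120) {
    op <- sample(c("add", "synonym", "rename"), 1)
    nm <- random_name()
    res <- tryCatch(switch(op,
      add = add_accessions(st, data.frame(name = nm, species = "Zea mays")),
      synonym = suppressWarnings(
        add_synonym(st, sample(st$accessions$name, 1), nm)),
      rename = rename_accession(st, sample(st$accessions$name, 1), nm)),
      bb_error = function(e) NULL, error = function(e) NULL)
    keys <- c(st$accessions$norm,
              # synonyms equal to their own accession's key are aliases,
              # not distinct claims on the namespace
              st$synonyms$norm[st$synonyms$norm !=
                st$accessions$norm[match(st$synonyms$accession_id, st$accessions$id)]])
    expect_equal(anyDuplicated(keys), 0)
  }
})

test_that("the three-role authorization matrix matches the platform rules", {
  st <- create_store()
  add_breeding_program(st, "IITA")
  add_user(st, "reader", "user")
  add_user(st, "sub", c("submitter", "program:IITA"))
  add_user(st, "sub2", "submitter")
  add_user(st, "cur", "curator")

  # user: read-only
  expect_true(authorize(st, "reader", "read", "other"))
  for (a in c("create", "update", "delete"))
    expect_false(authorize(st, "reader", a, "reader"))
  # submitter: create; update/delete only own uploads
  expect_true(authorize(st, "sub", "create"))
  expect_true(authorize(st, "sub", "update", object_owner = "sub"))
  expect_true(authorize(st, "sub", "delete", object_owner = "sub"))
  expect_false(authorize(st, "sub", "update", object_owner = "other"))
  expect_false(authorize(st, "sub", "delete", object_owner = "other"))
  # program scoping: creating in a program needs the program role
  expect_true(authorize(st, "sub", "create", object_program = "IITA"))
  expect_false(authorize(st, "sub2", "create", object_program = "IITA"))
  expect_true(authorize(st, "sub", "update", object_owner = "sub",
                        object_program = "IITA"))
  # curator: everything
  for (a in c("read", "create", "update", "delete"))
    expect_true(authorize(st, "cur", a, object_owner = "other",
                          object_program = "IITA"))
  expect_error(authorize(st, "cur", "fly"), class = "bb_unknown_action")
})

user_roles_of <- function(st, u) st$user_roles$role[st$user_roles$username == u]

test_that("authorization is monotone in roles", {
  st <- create_store()
  add_breeding_program(st, "IITA")
  role_sets <- list("user", "submitter", "curator",
                    c("submitter", "program:IITA"),
                    c("submitter", "curator"))
  cases <- expand.grid(action = c("read", "create", "update", "delete"),
                       owner = c("self", "other"),
                       prog = c(NA, "IITA"), stringsAsFactors = FALSE)
  for (i in seq_along(role_sets)) {
    u <- paste0("u", i)
    add_user(st, u, role_sets[[i]])
  }
  extra <- c("submitter", "curator", "program:IITA")
  for (i in seq_along(role_sets)) {
    u <- paste0("u", i)
    base <- apply(cases, 1, function(cs)
      authorize(st, u, cs[["action"]],
                object_owner = if (cs[["owner"]] == "self") u else "other",
                object_program = if (is.na(cs[["prog"]])) NULL else cs[["prog"]]))
    for (r in setdiff(extra, user_roles_of(st, u))) {
      u2 <- paste0(u, "_plus_", gsub("[^a-z]", "", r))
      add_user(st, u2, c(role_sets[[i]], r))
      more <- apply(cases, 1, function(cs)
        authorize(st, u2, cs[["action"]],
                  object_owner = if (cs[["owner"]] == "self") u2 else "other",
                  object_program = if (is.na(cs[["prog"]])) NULL else cs[["prog"]]))
      expect_true(all(more >= base),
                  label = sprintf("adding role %s never revokes an allow", r))
    }
  }
})

test_that("accession CSV upload stores passport properties and synonyms", {
  st <- create_store()
  csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "accession_name,species_name,synonyms,variety,donor,donor_institute,donor_PUI,country_of_origin,institute_code,institute_name,notes,accession_number,PUI",
    "TX303,Zea mays,Tx 303|TX303-A,landrace,CIMMYT,,,Mexico,,,old line,ACC-1,",
    "TMS30572,Manihot esculenta,,,,,,Nigeria,,,,,"), csv)
  r <- add_accessions(st, read_accession_csv(csv))
  expect_equal(nrow(r$created), 2)
  props <- accession_properties(st, "TX303")
  expect_equal(unname(props["variety"]), "landrace")
  expect_equal(unname(props["country_of_origin"]), "Mexico")
  expect_setequal(accession_synonyms(st, "TX303"), c("Tx 303", "TX303-A"))
  expect_equal(find_accession(st, "TX303A")$name, "TX303")
})
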