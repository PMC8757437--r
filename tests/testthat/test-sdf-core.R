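# Parsing, writing and grouping of SDfiles.

test_that("scalar coercion tries int, then float, then string", {
  expect_identical(coerce_scalar("42"), 42L)
  expect_identical(coerce_scalar("-7"), -7L)
  expect_identical(coerce_scalar("174.05"), 174.05)
  expect_identical(coerce_scalar("1e3"), 1000)
  expect_identical(coerce_scalar("1e3x"), "1e3x")
  expect_identical(coerce_scalar("abc"), "abc")
  # int-parseable tokens are never stored as float or string
  for (tok in c("0", "12", "-3", "+8")) {
    v <- coerce_scalar(tok)
    expect_true(is.integer(v), info = tok)
  }
})

test_that("data items detect single, list and dict structures", {
  mv <- parse_data_item(">  <mol_weight>", "174.05")
  expect_identical(mv$structure, "single")
  expect_identical(mv$dtype, "float")
  expect_identical(mv$payload, 174.05)

  mv <- parse_data_item(">  <dists>", "1:2.41 7:1.98")
  expect_identical(mv$structure, "dict")
  expect_identical(mv$keys, c(1L, 7L))
  expect_identical(mv$payload, c(2.41, 1.98))

  mv <- parse_data_item(">  <tag>", "abc")
  expect_identical(mv$structure, "single")
  expect_identical(mv$dtype, "string")

  # mixed coercions degrade the whole item to string
  mv <- parse_data_item(">  <mix>", "1 2.5 x")
  expect_identical(mv$dtype, "string")
  expect_identical(mv$payload, c("1", "2.5", "x"))

  # empty body means no metadata at all
  expect_null(parse_data_item(">  <empty>", character(0)))
})

test_that("an entry without data items parses to an empty meta map", {
  ens <- read_sdf(sdf_entry("M1", water_atoms()))
  expect_identical(length(ens), 1L)
  expect_length(ens$records[[1]]$meta, 0L)
  expect_identical(ens$records[[1]]$molfile$atoms$element, c("O", "H", "H"))
})

test_that("parse errors name the offending entry", {
  good <- sdf_entry("A", water_atoms())
  bad_counts <- sub(" {2}3 {2}2", "  9  2", good)   # atom count mismatch
  expect_error(read_sdf(paste(good, bad_counts, sep = "\n")), "entry 2")
  expect_error(read_sdf(c("JUSTONELINE")), "\\$\\$\\$\\$")
})

test_that("grouping and conformation numbering follow file order", {
  entries <- unlist(lapply(1:3, function(g)
    replicate(4, sdf_entry(sprintf("MOL%d", g), water_atoms()))))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  expect_identical(length(ens$groups), 3L)
  expect_identical(unname(lengths(ens$groups)), rep(4L, 3))
  for (idx in ens$groups)
    expect_identical(vapply(ens$records[idx], function(r) r$conf_number, integer(1)), 1:4)
  # partition: every record in exactly one group
  expect_identical(sort(unlist(ens$groups, use.names = FALSE)), seq_len(12L))
})

test_that("conformation tags encode, decode and survive numbering", {
  expect_identical(encode_conf_tag("CHEMBL100231", 3), "CHEMBL100231{[conf|3]}")
  expect_identical(decode_conf_tag("CHEMBL100231"),
                   list(name = "CHEMBL100231", conf = NA_integer_))
  # decode(encode(x, n)) == (x, n) across assorted names
  set.seed(42)
  for (k in 1:50) {
    nm <- paste(sample(c(LETTERS, letters, 0:9, "_", "-"), sample(3:20, 1),
                       replace = TRUE), collapse = "")
    n <- sample(1:99, 1)
    expect_identical(decode_conf_tag(encode_conf_tag(nm, n)),
                     list(name = nm, conf = as.integer(n)))
  }
  # malformed tag is a plain name
  expect_identical(decode_conf_tag("X{[conf|3]")$conf, NA_integer_)

  # an encoded number wins over sequential assignment
  entries <- c(sdf_entry("A", water_atoms()),
               sdf_entry("A{[conf|7]}", water_atoms()),
               sdf_entry("A", water_atoms()))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  expect_identical(vapply(ens$records, function(r) r$conf_number, integer(1)),
                   c(1L, 7L, 2L))
  # duplicate encoded pairs are an error naming both entries
  dup <- paste(sdf_entry("A{[conf|2]}", water_atoms()),
               sdf_entry("A{[conf|2]}", water_atoms()), sep = "\n")
  expect_error(read_sdf(dup), "1, 2")
})

test_that("write/parse round trip is the identity and emits one $$$$ per record", {
  ens <- random_meta_ensemble(3, 4, seed = 11, with_dicts = TRUE)
  txt <- write_sdf(ens)
  expect_identical(lengths(regmatches(txt, gregexpr("\\$\\$\\$\\$", txt))), 12L)
  rt <- read_sdf(txt)
  expect_true(confmeta:::ensembles_identical(ens, rt))
  # and again through a tagged write
  rt2 <- read_sdf(write_sdf(ens, tag_names = TRUE))
  expect_true(confmeta:::ensembles_identical(ens, rt2))
  # empty ensemble serializes to zero bytes
  expect_identical(write_sdf(read_sdf(character(0))), "")
})

test_that("dict, list and awkward string values survive serialization", {
  entry <- sdf_entry("M", water_atoms(),
                     meta = list(d = "1:0.5 2:abc 3:x",
                                 l = "1 2 3",
                                 s = "[single] free text with spaces, and 1:colon"))
  ens <- read_sdf(entry)
  m <- ens$records[[1]]$meta
  expect_identical(m$d$structure, "dict")
  expect_identical(m$d$dtype, "string")        # mixed values degrade
  expect_identical(m$l$payload, 1:3)
  expect_identical(m$s$structure, "single")
  expect_identical(m$s$payload, "free text with spaces, and 1:colon")
  rt <- read_sdf(write_sdf(ens))
  expect_true(confmeta:::ensembles_identical(ens, rt))
})

test_that("long data-item bodies wrap on write and re-join on read", {
  keys <- 1:40
  body <- paste(sprintf("%d:%s", keys, sprintf("%.10f", sqrt(keys))), collapse = " ")
  ens <- read_sdf(sdf_entry("M", water_atoms(), meta = list(big = body)))
  txt <- write_sdf(ens)
  expect_true(all(nchar(strsplit(txt, "\n")[[1]]) <= 200))
  rt <- read_sdf(txt)
  expect_true(confmeta:::ensembles_identical(ens, rt))
})

test_that("regroup rebuilds groups on a metafield and renumbers", {
  entries <- unlist(lapply(1:6, function(i)
    sdf_entry(sprintf("E%d", i), water_atoms(),
              meta = list(real_id = sprintf("MOL%d", (i - 1) %% 2 + 1)))))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  expect_identical(length(ens$groups), 6L)
  ens2 <- regroup(ens, "real_id")
  expect_identical(length(ens2$groups), 2L)
  expect_identical(unname(lengths(ens2$groups)), c(3L, 3L))
  for (idx in ens2$groups)
    expect_identical(vapply(ens2$records[idx], function(r) r$conf_number, integer(1)), 1:3)
  # regrouping by a constant-valued field gives one group
  ens3 <- regroup(new_meta(ens, "const", "1"), "const")
  expect_identical(length(ens3$groups), 1L)
  # a record lacking the field is an error naming it
  expect_error(regroup(remove_meta(ens, "real_id"), "real_id"), "record 1")
})

test_that("a full campaign-scale file of 99 molecules x 10 conformers groups correctly", {
  fx <- generate_fixture(99, 10, seed = 3)
  ens <- read_sdf(fx$sdf)
  ens <- regroup(store_header_as_meta(import_csv(ens, fx$corresponding_names),
                                      "plants_id"), "OLD_LIGAND_DESCRIPTION")
  expect_identical(length(ens$groups), 99L)
  for (idx in ens$groups)
    expect_identical(sort(vapply(ens$records[idx], function(r) r$conf_number, integer(1))),
                     1:10)
})
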