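# The metastatement language: parsing, evaluation, builtins.

test_that("parser builds the documented precedence and node kinds", {
  ast <- parse_statement("score/mmax(score)")
  expect_identical(ast$kind, "binop")
  expect_identical(ast$op, "/")
  expect_identical(ast$lhs, list(kind = "ref", name = "score"))
  expect_identical(ast$rhs$kind, "call")
  expect_identical(ast$rhs$fun, "mmax")

  ast <- parse_statement("glutadist(<=2.5)")
  expect_identical(ast$kind, "slice")
  expect_identical(ast$cmp, "<=")
  expect_identical(ast$threshold$value, 2.5)
  # the Unicode comparator glyph parses to the same tree
  expect_identical(parse_statement("glutadist(≤2.5)"), ast)

  ast <- parse_statement("close_atoms{}")
  expect_identical(ast$kind, "key_extract")
  expect_identical(ast$x$name, "close_atoms")

  ast <- parse_statement("atom_types(close_atom_nums)")
  expect_identical(ast$kind, "key_index")

  # precedence: unary minus > * / > + - > comparison
  ast <- parse_statement("-a*b+c<=d")
  expect_identical(ast$op, "<=")
  expect_identical(ast$lhs$op, "+")
  expect_identical(ast$lhs$lhs$op, "*")
  expect_identical(ast$lhs$lhs$lhs$kind, "neg")

  expect_error(parse_statement("a+(b"), "syntax error")
  expect_error(parse_statement("a ~ b"), "character 3")
})

test_that("parse-unparse-parse is the identity on the syntax tree", {
  stmts <- c("score/mmax(score)", "glutadist(<=2.5)", "close_atoms{}",
             "atom_types(close_atom_nums)", "9-log10(IC50_nM)",
             "mrank(TOTAL_SCORE)<=0.3*mcount()", "pow(a, 2)+sqrt(b)/ln(c)",
             'plants_id-"_entry_\\d+_conf_\\d+"',
             "a(=O) & b(=H) | c(!=0)", "-x*(y+2)")
  for (s in stmts) {
    ast <- parse_statement(s)
    expect_identical(parse_statement(unparse_statement(ast)), ast, info = s)
  }
})

test_that("evaluation lifts arithmetic over lists and dicts", {
  ens <- read_sdf(sdf_entry("M", water_atoms(),
                            meta = list(d = "1:4.0 2:6.0", l = "1 2 3", s = "5")))
  ev <- function(stmt) evaluate_statement(stmt, ens)[[1]]
  expect_meta_equal(ev("d/2"), meta_value(c(2, 3), "dict", keys = 1:2))
  expect_meta_equal(ev("10-d"), meta_value(c(6, 4), "dict", keys = 1:2))
  expect_meta_equal(ev("l*2"), meta_value(c(2L, 4L, 6L), "list"))
  expect_meta_equal(ev("s+1"), meta_value(6L))
  expect_meta_equal(ev("2.5"), meta_value(2.5))
  # dict op dict joins on keys (inner join)
  ens2 <- read_sdf(sdf_entry("M", water_atoms(),
                             meta = list(a = "1:10.0 2:20.0 3:30.0", b = "2:2.0 3:3.0 9:9.0")))
  got <- evaluate_statement("a/b", ens2)[[1]]
  expect_equal(got$keys, c(2, 3))
  expect_identical(got$payload, c(10, 10))
  # division by zero is ABSENT, not a crash
  ens3 <- read_sdf(sdf_entry("M", water_atoms(), meta = list(z = "0")))
  expect_true(is_absent(evaluate_statement("1/z", ens3)[[1]]))
})

test_that("missing metadata makes the whole statement ABSENT for that record", {
  entries <- c(sdf_entry("A", water_atoms(), meta = list(score = "3.0")),
               sdf_entry("B", water_atoms()))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  res <- evaluate_statement("score*2+1", ens)
  expect_identical(res[[1]]$payload, 7)
  expect_true(is_absent(res[[2]]))
  # ABSENT monotonicity: wrapping the missing ref deeper cannot create a value
  for (stmt in c("score", "score+1", "log10(score)", "mmax(score)-score",
                 "score(<=10)", "pow(score, 2)"))
    expect_true(is_absent(evaluate_statement(stmt, ens)[[2]]), info = stmt)
})

test_that("aggregates match brute-force reductions at both scopes", {
  set.seed(101)
  for (case in 1:25) {
    ens <- random_meta_ensemble(n_groups = sample(2:5, 1), n_confs = sample(1:5, 1),
                                seed = 100 + case)
    vals <- vapply(meta_column(ens, "score"), identity, numeric(1))
    gid <- ens_group_ids(ens)
    for (fun in c("max", "min", "avg", "sum")) {
      stat <- switch(fun, max = max, min = min, avg = mean, sum = sum)
      got_file <- vapply(evaluate_statement(sprintf("%s(score)", fun), ens),
                         function(x) x$payload, numeric(1))
      expect_equal(got_file, rep(stat(vals), length(vals)), info = fun)
      got_grp <- vapply(evaluate_statement(sprintf("m%s(score)", fun), ens),
                        function(x) x$payload, numeric(1))
      expect_equal(got_grp, as.numeric(ave(vals, gid, FUN = stat)), info = fun)
    }
  }
  # on a 1-group file, max and mmax coincide
  ens1 <- random_meta_ensemble(1, 6, seed = 9)
  expect_identical(vapply(evaluate_statement("max(score)", ens1), `[[`, numeric(1), "payload"),
                   vapply(evaluate_statement("mmax(score)", ens1), `[[`, numeric(1), "payload"))
})

test_that("dict arguments to aggregates reduce per record first", {
  entries <- c(sdf_entry("A", water_atoms(), meta = list(d = "1:1.0 2:5.0")),
               sdf_entry("A", water_atoms(), meta = list(d = "1:3.0 2:4.0")))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  got <- vapply(evaluate_statement("mmax(d)", ens), `[[`, numeric(1), "payload")
  expect_identical(got, c(5, 5))
  # per-record sums 6 and 7, then summed over the group
  got <- vapply(evaluate_statement("msum(d)", ens), `[[`, numeric(1), "payload")
  expect_identical(got, c(13, 13))
})

test_that("group normalization reaches exactly 1.0 in every group", {
  ens <- random_meta_ensemble(5, 4, seed = 77)
  res <- vapply(evaluate_statement("score/mmax(score)", ens), `[[`, numeric(1), "payload")
  gid <- ens_group_ids(ens)
  expect_true(all(res > 0 & res <= 1))
  expect_identical(as.vector(tapply(res, gid, max)), rep(1, 5))
})

test_that("slicing keeps passing entries and obeys the identity cases", {
  v <- meta_value(c(2.41, 2.62, 1.97), "dict", keys = c(3L, 9L, 15L))
  got <- slice_by_value(v, "<=", 2.5)
  expect_identical(got$keys, c(3L, 15L))
  expect_identical(got$payload, c(2.41, 1.97))
  expect_true(is_absent(slice_by_value(meta_value(3.0), "<=", 2.5)))
  expect_identical(slice_by_value(meta_value(2.0), "<=", 2.5)$payload, 2)
  # pass-all threshold returns the input unchanged; pass-none is ABSENT
  expect_identical(slice_by_value(v, "<=", Inf)$payload, v$payload)
  expect_true(is_absent(slice_by_value(v, ">", Inf)))
  # string equality slices (SYBYL types)
  s <- meta_value(c("O.3", "H", "C.3"), "dict", keys = 1:3)
  expect_identical(slice_by_value(s, "=", "O.3")$keys, 1L)
  expect_true(is_absent(slice_by_value(s, "<", "O.3")))
  # brute-force filter oracle on random dicts
  set.seed(5)
  for (k in 1:200) {
    n <- sample(1:8, 1)
    vals <- round(runif(n, 0, 5), 3)
    thr <- runif(1, 0, 5)
    cmp <- sample(c("<", "<=", ">", ">=", "=", "!="), 1)
    keep <- switch(cmp, "<" = vals < thr, "<=" = vals <= thr, ">" = vals > thr,
                   ">=" = vals >= thr, "=" = vals == thr, "!=" = vals != thr)
    got <- slice_by_value(meta_value(vals, "dict", keys = seq_len(n)), cmp, thr)
    if (!any(keep)) expect_true(is_absent(got))
    else expect_identical(got$payload, vals[keep])
  }
})

test_that("key extraction and key indexing restrict dictionaries", {
  d <- meta_value(c(2.41, 1.97), "dict", keys = c(3L, 15L))
  expect_identical(key_extract(d)$payload, c(3L, 15L))
  expect_identical(key_extract(d)$structure, "list")
  expect_identical(key_extract(meta_value(1.5, "dict", keys = 7L))$payload, 7L)
  expect_warning(got <- key_extract(meta_value(1:3, "list")))
  expect_true(is_absent(got))

  at <- meta_value(c("C", "O", "H"), "dict", keys = c(1L, 3L, 7L))
  got <- key_index(at, meta_value(c(3L, 7L), "list"))
  expect_identical(got$payload, c("O", "H"))
  expect_identical(got$keys, c(3L, 7L))
  # missing keys skip silently; empty selection is ABSENT
  expect_identical(key_index(at, meta_value(c(3L, 99L), "list"))$keys, 3L)
  expect_true(is_absent(key_index(at, meta_value(99L, "list"))))
})

test_that("string subtraction removes every regex match", {
  expect_identical(
    regex_subtract("CHEMBL100231_entry_00042_conf_01", "_entry_\\d+_conf_\\d+"),
    "CHEMBL100231")
  expect_identical(regex_subtract("abc", "$a"), "abc")
  expect_identical(regex_subtract("abcabc", "b"), "acac")
  expect_error(regex_subtract("x", "("), "invalid regular expression")
  # oracle: agree with gsub on random inputs
  set.seed(8)
  for (k in 1:100) {
    s <- paste(sample(c(letters[1:4], "_", "1"), 12, replace = TRUE), collapse = "")
    p <- sample(c("a+", "b", "_\\d", "[ab]c", "a.c"), 1)
    expect_identical(regex_subtract(s, p), gsub(p, "", s, perl = TRUE))
  }
  # string + concatenates; other ops are ABSENT
  ens <- read_sdf(sdf_entry("M", water_atoms(), meta = list(a = "foo", b = "oo")))
  expect_identical(evaluate_statement('a+"_x"', ens)[[1]]$payload, "foo_x")
  expect_identical(evaluate_statement("a-b", ens)[[1]]$payload, "f")
  expect_warning(res <- evaluate_statement("a*b", ens))
  expect_true(is_absent(res[[1]]))
})

test_that("confcol returns atom-block columns keyed by atom number", {
  ens <- read_sdf(sdf_entry("W", water_atoms()))
  got <- evaluate_statement("confcol(4)", ens)[[1]]
  expect_identical(got$structure, "dict")
  expect_identical(got$keys, 1:3)
  expect_identical(got$payload, c("O", "H", "H"))
  xs <- evaluate_statement("confcol(1)", ens)[[1]]
  expect_identical(xs$dtype, "float")
  expect_equal(xs$payload, water_atoms()$x)
  expect_error(evaluate_statement("confcol(99)", ens), "column")
})

test_that("math builtins act elementwise and guard their domains", {
  ens <- read_sdf(sdf_entry("M", water_atoms(),
                            meta = list(IC50_nM = "1", v = "1:100.0 2:0.01", neg = "-4")))
  expect_identical(evaluate_statement("9-log10(IC50_nM)", ens)[[1]]$payload, 9)
  expect_identical(evaluate_statement("log10(1)", ens)[[1]]$payload, 0)
  expect_identical(evaluate_statement("log10(1000)", ens)[[1]]$payload, 3)
  got <- evaluate_statement("log10(v)", ens)[[1]]
  expect_equal(got$payload, c(2, -2))
  expect_identical(got$keys, 1:2)
  expect_true(is_absent(evaluate_statement("log10(0)", ens)[[1]]))
  expect_true(is_absent(evaluate_statement("sqrt(neg)", ens)[[1]]))
  expect_identical(evaluate_statement("abs(neg)", ens)[[1]]$payload, 4L)
  expect_identical(evaluate_statement("pow(neg, 2)", ens)[[1]]$payload, 16)
  expect_identical(evaluate_statement("ln(pow(IC50_nM, 5))", ens)[[1]]$payload, 0)
})

test_that("mrank and mcount rank within groups with deterministic ties", {
  entries <- c(sdf_entry("A", water_atoms(), meta = list(s = "5.0")),
               sdf_entry("A", water_atoms(), meta = list(s = "3.0")),
               sdf_entry("A", water_atoms(), meta = list(s = "4.0")),
               sdf_entry("B", water_atoms(), meta = list(s = "1.0")))
  ens <- read_sdf(paste(entries, collapse = "\n"))
  ranks <- vapply(evaluate_statement("mrank(s)", ens), `[[`, integer(1), "payload")
  expect_identical(ranks, c(3L, 1L, 2L, 1L))
  counts <- vapply(evaluate_statement("mcount()", ens), `[[`, integer(1), "payload")
  expect_identical(counts, c(3L, 3L, 3L, 1L))
  # ties break by conformation number
  tied <- read_sdf(paste(replicate(3, sdf_entry("T", water_atoms(), meta = list(s = "2.0"))),
                         collapse = "\n"))
  expect_identical(vapply(evaluate_statement("mrank(s)", tied), `[[`, integer(1), "payload"),
                   1:3)
  # a 30% cut on 10 conformers keeps exactly 3
  ens10 <- random_meta_ensemble(1, 10, seed = 33)
  kept <- filter_records(ens10, "mrank(score)<=0.3*mcount()")
  expect_identical(length(kept), 3L)
  vals <- vapply(meta_column(ens10, "score"), identity, numeric(1))
  expect_identical(sort(vapply(meta_column(kept, "score"), identity, numeric(1))),
                   sort(vals)[1:3])
})

test_that("builtins agree with brute-force oracles on seeded random fixtures", {
  # one deep parameterised sweep: aggregates, slices, key ops, arithmetic
  set.seed(2024)
  n_cases <- 0L
  for (rep in 1:60) {
    ens <- random_meta_ensemble(n_groups = sample(2:4, 1), n_confs = sample(2:4, 1),
                                seed = 5000 + rep, with_dicts = TRUE)
    gid <- ens_group_ids(ens)
    scores <- vapply(meta_column(ens, "score"), identity, numeric(1))
    dicts <- meta_column(ens, "dvals")
    lists <- meta_column(ens, "lvals")

    thr <- round(runif(1, 0, 5), 2)
    got <- evaluate_statement(sprintf("dvals(<=%s)", num_str(thr)), ens)
    for (i in seq_along(got)) {
      keep <- unlist(dicts[[i]]) <= thr
      if (!any(keep)) expect_true(is_absent(got[[i]]))
      else expect_equal(unname(got[[i]]$payload), unname(unlist(dicts[[i]])[keep]))
      n_cases <- n_cases + 1L
    }

    got <- evaluate_statement("dvals{}", ens)
    for (i in seq_along(got)) {
      expect_equal(as.character(got[[i]]$payload), names(dicts[[i]]))
      n_cases <- n_cases + 1L
    }

    got <- evaluate_statement("score/mmax(score)+mavg(lvals)", ens)
    for (i in seq_along(got)) {
      grp <- gid == gid[i]
      exp_val <- scores[i] / max(scores[grp]) + mean(vapply(lists[grp], mean, numeric(1)))
      expect_equal(got[[i]]$payload, exp_val)
      n_cases <- n_cases + 1L
    }

    got <- evaluate_statement("dvals(close_nums)", ens)  # close_nums missing -> ABSENT
    expect_true(all(vapply(got, is_absent, logical(1))))

    got <- evaluate_statement("sum(score)-score*2", ens)
    for (i in seq_along(got)) {
      expect_equal(got[[i]]$payload, sum(scores) - scores[i] * 2)
      n_cases <- n_cases + 1L
    }
  }
  expect_gt(n_cases, 1000L)
})
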