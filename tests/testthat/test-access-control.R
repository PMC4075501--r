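acl_fixture <- function() {
  eng <- demo_engine()
  for (u in c("curator", "genetic", "clinical")) {
    eng$assign_patient_to_workgroup("DM1Unit", "dm1", "p1")
  }
  add_patient(eng, "dm1", "p1")
  put_value(eng, "dm1", "p1", "Height", 1.8)
  put_value(eng, "dm1", "p1", "Weight", 81)
  put_value(eng, "dm1", "p1", "CTGRepeatLength", 250)
  put_value(eng, "dm1", "p1", "RepeatExpansionSize", "medium")
  eng
}

test_that("admin bypasses every rule; others resolve most-specific-first", {
  eng <- acl_fixture()
  expect_true(can_access(eng, "admin", "dm1", "CTGRepeatLength", "write"))

  # clinical holds a wildcard read_write but an exact none on genetics fields
  expect_true(can_access(eng, "clinical", "dm1", "Height", "write"))
  expect_false(can_access(eng, "clinical", "dm1", "CTGRepeatLength", "read"))
  expect_false(can_access(eng, "clinical", "dm1", "RepeatExpansionSize", "read"))

  # curator: wildcard read, no write rule -> default deny on write
  expect_true(can_access(eng, "curator", "dm1", "Height", "read"))
  expect_false(can_access(eng, "curator", "dm1", "Height", "write"))
})

test_that("default deny: an empty rule table grants nothing to non-admins", {
  eng <- demo_engine()
  eng$set_rules(list())
  add_patient(eng, "dm1", "p1")
  for (u in c("curator", "genetic", "clinical")) {
    expect_false(can_access(eng, u, "dm1", "Height", "read"), label = u)
    expect_false(can_access(eng, u, "dm1", "Height", "write"), label = u)
    expect_equal(visible_patients(eng, u, "dm1"), character())
  }
  expect_true(can_access(eng, "admin", "dm1", "Height", "write"))
})

test_that("visible_patients is the union of the user's workgroups", {
  eng <- demo_engine()
  for (p in c("p1", "p2", "p3")) add_patient(eng, "dm1", p)
  eng$assign_patient_to_workgroup("WA", "dm1", "p1")
  eng$assign_patient_to_workgroup("WB", "dm1", "p2")
  eng$assign_patient_to_workgroup("WB", "dm1", "p1")
  add_user(eng, "alice", "clinical", c("WA", "WB"))
  add_user(eng, "bob", "clinical", "WB")
  add_user(eng, "carol", "clinical")
  expect_setequal(visible_patients(eng, "alice", "dm1"), c("p1", "p2"))
  expect_setequal(visible_patients(eng, "bob", "dm1"), c("p1", "p2"))
  expect_equal(visible_patients(eng, "carol", "dm1"), character())
  expect_setequal(visible_patients(eng, "admin", "dm1"), c("p1", "p2", "p3"))
})

test_that("view_document filters to readable elements without leaking", {
  eng <- acl_fixture()
  full <- view_document(eng, "admin", "dm1", "p1")
  clin <- view_document(eng, "clinical", "dm1", "p1")
  codes <- function(doc) sort(vapply(names(doc$entries), function(k)
    decode_record_key(k)$de_code, character(1), USE.NAMES = FALSE))
  expect_true(all(c("CTGRepeatLength", "RepeatExpansionSize") %in% codes(full)))
  expect_false(any(c("CTGRepeatLength", "RepeatExpansionSize") %in% codes(clin)))
  expect_true(all(c("Height", "Weight", "BMI") %in% codes(clin)))

  # outside the workgroup: hard error, no partial document
  add_user(eng, "outsider", "clinical")
  expect_error(view_document(eng, "outsider", "dm1", "p1"),
               class = "regkit_access_denied")
})

test_that("a derived element's readability is independent of its inputs'", {
  eng <- acl_fixture()
  eng$grant("clinical", "dm1", "Weight", "none")
  doc <- view_document(eng, "clinical", "dm1", "p1")
  codes <- vapply(names(doc$entries), function(k) decode_record_key(k)$de_code,
                  character(1), USE.NAMES = FALSE)
  expect_false("Weight" %in% codes)
  expect_true("BMI" %in% codes)   # BMI itself is readable even if Weight is not
})

rand_rules <- function(reg, codes, n) {
  lapply(seq_len(n), function(i) {
    list(role = sample(c("curator", "genetic", "clinical"), 1),
         registry = reg,
         de_code = sample(c("*", codes), 1),
         access = sample(c("none", "read", "read_write"), 1))
  })
}

test_that("view_document equals the brute-force filter oracle on random tables", {
  set.seed(1122)
  for (trial in 1:25) {
    eng <- demo_engine()
    codes <- c("DOB", "AgeAtOnset", "Height", "Weight", "BMI",
               "CTGRepeatLength", "RepeatExpansionSize", "InsuranceNumber")
    rules <- rand_rules("dm1", codes, sample(0:6, 1))
    eng$set_rules(rules)
    add_patient(eng, "dm1", "p1")
    put_value(eng, "dm1", "p1", "Height", 1.7)
    put_value(eng, "dm1", "p1", "Weight", 70)
    put_value(eng, "dm1", "p1", "AgeAtOnset", 33)
    eng$assign_patient_to_workgroup("W", "dm1", "p1")
    user <- sample(c("curator", "genetic", "clinical"), 1)
    add_user(eng, "tester", user, "W")

    full <- view_document(eng, "admin", "dm1", "p1")
    got <- view_document(eng, "tester", "dm1", "p1")
    keep <- vapply(names(full$entries), function(k) {
      oracle_access(rules, user, "dm1", decode_record_key(k)$de_code) >= 1
    }, logical(1))
    expect_identical(names(got$entries), names(full$entries)[keep])
    # and every per-element decision matches the oracle
    for (code in codes) {
      expect_equal(can_access(eng, "tester", "dm1", code, "read"),
                   oracle_access(rules, user, "dm1", code) >= 1, label = code)
      expect_equal(can_access(eng, "tester", "dm1", code, "write"),
                   oracle_access(rules, user, "dm1", code) >= 2, label = code)
    }
  }
})

test_that("grants are monotone: adding one never removes access", {
  set.seed(3344)
  codes <- c("A", "B", "C")
  for (trial in 1:60) {
    eng <- registry_engine()
    create_registry(eng, "r", "R", "1.0")
    for (code in codes) define_element(eng, code, datatype = "string")
    add_user(eng, "u", "clinical")
    base <- rand_rules("r", codes, sample(0:5, 1))
    eng$set_rules(base)
    before <- sapply(codes, function(c) {
      c(can_access(eng, "u", "r", c, "read"), can_access(eng, "u", "r", c, "write"))
    })
    # add a grant (never a deny)
    grant(eng, "clinical", "r", sample(c("*", codes), 1),
          sample(c("read", "read_write"), 1))
    after <- sapply(codes, function(c) {
      c(can_access(eng, "u", "r", c, "read"), can_access(eng, "u", "r", c, "write"))
    })
    expect_true(all(after >= before))
    # removing that grant never adds access relative to the grown state
    eng$set_rules(base)
    again <- sapply(codes, function(c) {
      c(can_access(eng, "u", "r", c, "read"), can_access(eng, "u", "r", c, "write"))
    })
    expect_true(all(again <= after))
  }
})
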