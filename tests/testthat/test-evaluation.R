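# Confusion tables and the built-in published-counts fixture.

fx <- paper_fixture()
fx_tab <- table1(fx, fx$label)

test_that("the fixture reproduces the published stratum sizes and flag counts", {
  expect_identical(as.vector(table(fx$label)[c("RS-P", "RS-NP", "HC")]),
                   c(31L, 45L, 28L))
  rsp <- fx[fx$label == "RS-P", ]
  expect_identical(sum(rsp$flag_onh & rsp$flag_mac), 11L)
  expect_identical(sum(rsp$flag_onh & !rsp$flag_mac), 5L)
  expect_identical(sum(!rsp$flag_onh & rsp$flag_mac), 11L)
  expect_identical(sum(!rsp$flag_onh & !rsp$flag_mac), 4L)
  hc <- fx[fx$label == "HC", ]
  expect_identical(sum(hc$flag_onh), 2L)
  expect_identical(sum(hc$flag_mac), 6L)
  expect_identical(sum(hc$flag_onh & hc$flag_mac), 1L)
  expect_identical(sum(fx$flag_5um[fx$label == "RS-P"]), 10L)
  expect_identical(sum(fx$flag_5um[fx$label == "HC"]), 0L)
})

test_that("single-rule confusion rows match the published table", {
  onh <- confusion(fx, fx$label, "ONH")
  expect_identical(onh$fn_count, 15L)
  expect_identical(onh$fp_patient_count, 8L)
  expect_equal(onh$fn_rate, 48.4)   # 15/31; the table's 48.3 is a known misprint
  expect_equal(onh$fp_patient_rate, 17.8)
  expect_equal(onh$accuracy, 69.7)
  expect_equal(onh$fp_hc_rate, 7.1)
  mac <- confusion(fx, fx$label, "MAC")
  expect_equal(c(mac$fn_rate, mac$fp_patient_rate, mac$accuracy,
                 mac$fp_hc_rate), c(29.0, 6.7, 84.2, 21.4))
})

test_that("combined and fixed rules match the published table", {
  or <- confusion(fx, fx$label, "OR")
  expect_equal(c(or$fn_rate, or$fp_patient_rate, or$accuracy, or$fp_hc_rate),
               c(12.9, 22.2, 81.6, 25.0))
  and <- confusion(fx, fx$label, "AND")
  expect_equal(and$fn_rate, 64.5)
  expect_equal(and$accuracy, 72.4)
  five <- confusion(fx, fx$label, "FIXED5")
  expect_equal(c(five$fn_rate, five$fp_patient_rate, five$accuracy,
                 five$fp_hc_rate), c(67.7, 8.9, 67.1, 0))
})

test_that("inclusion-exclusion ties the OR and AND columns to the singles", {
  for (lab in c("RS-P", "RS-NP", "HC")) {
    s <- fx[fx$label == lab, ]
    expect_identical(sum(s$flag_or),
                     sum(s$flag_onh) + sum(s$flag_mac) -
                       sum(s$flag_onh & s$flag_mac))
    expect_identical(sum(s$flag_and),
                     sum(s$flag_onh & s$flag_mac))
  }
  # AND FNs = missed by one OR both = FN_onh + FN_mac - missed-by-both
  rsp <- fx[fx$label == "RS-P", ]
  expect_identical(sum(!rsp$flag_and),
                   sum(!rsp$flag_onh) + sum(!rsp$flag_mac) -
                     sum(!rsp$flag_onh & !rsp$flag_mac))
})

test_that("every printed percentage re-derives from its count to one decimal", {
  expected <- list(
    ONH = c(48.4, 17.8, 69.7, 7.1),  # 48.3 printed; 15/31 rounds to 48.4
    MAC = c(29.0, 6.7, 84.2, 21.4),
    OR = c(12.9, 22.2, 81.6, 25.0),
    AND = c(64.5, 2.2, 72.4, 3.6),   # HC cell from the text's both=1
    FIXED5 = c(67.7, 8.9, 67.1, 0))
  for (r in names(expected)) {
    row <- fx_tab[fx_tab$rule == r, ]
    expect_equal(c(row$fn_rate, row$fp_patient_rate, row$accuracy,
                   row$fp_hc_rate), expected[[r]])
  }
})

test_that("degenerate call sets give the boundary tables", {
  none <- fx
  none[c("flag_onh", "flag_mac", "flag_or", "flag_and", "flag_5um")] <- FALSE
  tab <- table1(none, none$label)
  expect_true(all(tab$fn_rate == 100))
  expect_true(all(tab$fp_patient_rate == 0) && all(tab$fp_hc_rate == 0))
  perfect <- fx
  perfect[c("flag_onh", "flag_mac", "flag_or", "flag_and",
            "flag_5um")] <- fx$label == "RS-P"
  tab2 <- table1(perfect, perfect$label)
  expect_true(all(tab2$accuracy == 100))
  expect_true(all(tab2$fn_count == 0L) && all(tab2$fp_patient_count == 0L))
})

test_that("label and column contracts are enforced", {
  expect_error(confusion(fx, rep("X", nrow(fx)), "ONH"), "labels")
  expect_error(confusion(fx, fx$label[-1], "ONH"), "one entry")
  expect_error(confusion(fx[, 1:2], fx$label, "ONH"), "missing column")
  expect_error(confusion(fx, fx$label, "BAD"), "unknown rule")
})

test_that("rounding is half-up as in clinical tables", {
  expect_identical(round_half_up(12.25, 1), 12.3)
  expect_identical(round_half_up(48.387, 1), 48.4)
  expect_identical(round_half_up(-2.45, 1), -2.5)
  expect_identical(format_table1(fx_tab)["Accuracy (n = 76)", "ONH"],
                   "69.7% (23)")
})
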