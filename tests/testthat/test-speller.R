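test_that("scan schedule: pre-selection steps precede row 0 and the cycle wraps", {
  lay <- default_speller_layout()     # 3 pre-selection rows, rate 1.5/s
  st <- scan_state(lay)
  expect_equal(scan_highlight(st), -3)
  st2 <- advance_scan(st, 2.0)        # 3 pre-steps x (1/1.5 s) = 2.0 s
  expect_equal(scan_highlight(st2), 0)
  expect_equal(scan_highlight(advance_scan(st, 0)), -3)
  period <- (3 + length(lay$rows)) / 1.5
  expect_equal(scan_highlight(advance_scan(st, period)), -3)
  expect_error(advance_scan(st, -1), ">= 0")
})

test_that("two clicks type a letter; DEL pops; pre-selection clicks are ignored", {
  lay <- default_speller_layout()
  st <- scan_state(lay, lexicon = NULL)
  # click during pre-selection does nothing
  expect_equal(apply_click(st)$phase, "row")
  # select row 2 (A-F row), then key "A" (column 2 after the suggestion slot)
  st <- advance_scan(st, (3 + 1) / 1.5 + 0.01)
  st <- apply_click(st)
  expect_equal(st$phase, "col")
  expect_equal(st$selected_row, 2L)
  st <- advance_scan(st, (1 + 1) / 1.5 + 0.01)
  st <- apply_click(st)
  expect_equal(st$typed_text, "A")
  expect_equal(st$phase, "row")
  # type B then DEL
  type_key <- function(st, row, col) {
    st <- advance_scan(st, (3 + row - 1) / 1.5 + 0.01)
    st <- apply_click(st)
    st <- advance_scan(st, (1 + col - 1) / 1.5 + 0.01)
    apply_click(st)
  }
  st <- type_key(st, 2, 3)    # "B"
  expect_equal(st$typed_text, "AB")
  st <- type_key(st, 6, 5)    # DEL
  expect_equal(st$typed_text, "A")
})

test_that("autocomplete ranks prefix matches by frequency", {
  lex <- c(THE = 100, THAT = 50, CAT = 10)
  expect_equal(autocomplete("TH", lex, 3), c("THE", "THAT"))
  expect_equal(autocomplete("", lex, 2), c("THE", "THAT"))
  expect_identical(autocomplete("TH", lex), autocomplete("TH", lex))
  expect_error(autocomplete("A", numeric(0)), "empty lexicon")
})

test_that("word completion substitutes the partial word; A-DEL removes the last word", {
  lay <- default_speller_layout()
  lex <- c(WATER = 5, WAS = 3)
  st <- scan_state(lay, lexicon = lex)
  st$typed_text <- "THE WAT"
  # word slot 1 shows WATER; clicking it completes the word plus a space
  st$phase <- "col"; st$selected_row <- 1L; st$phase_start <- st$t
  st <- advance_scan(st, 1 / 1.5 + 0.01)   # 1 pre-selection column, slot 1
  st <- apply_click(st)
  expect_equal(st$typed_text, "THE WATER ")
  expect_equal(st$last_kind, "word-autocomplete")
  # A-DEL removes the whole autocompleted word
  st$phase <- "col"; st$selected_row <- 6L; st$phase_start <- st$t
  st <- advance_scan(st, (1 + 5) / 1.5 + 0.01)  # A-DEL at column 6
  st <- apply_click(st)
  expect_equal(st$typed_text, "THE ")
})

test_that("ideal closed loop reproduces the prompt exactly at the analytic pace", {
  lay <- default_speller_layout()
  res <- simulate_session(lay, "BE BAD", user = user_model(0, 0),
                          detector = "ideal", lexicon = NULL, seed = 3)
  expect_equal(res$transcripts, "BE BAD")
  # independent step-schedule oracle: letters only (no autocomplete slots)
  key_pos <- function(ch) {
    for (r in seq_along(lay$rows)) {
      hit <- which(lay$rows[[r]] == ch & lay$kinds[[r]] %in% c("letter", "SPACE"))
      if (length(hit)) return(c(r, hit[1]))
    }
  }
  plan <- c(lapply(strsplit("BE BAD", "")[[1]],
                   function(ch) key_pos(if (ch == " ") "SPACE" else ch)),
            list(c(6, 7)))   # ENTER
  step <- 1 / 1.5
  expected <- sum(vapply(plan, function(p) {
    (3 + p[1] - 1) * step + (1 + p[2] - 1) * step
  }, 0))
  expect_equal(res$durations_s, expected, tolerance = 1e-6)
  # spelling score: everything correct
  expect_equal(res$scores[[1]]$n_correct_chars, 6)
})

test_that("word suggestions accelerate spelling in the ideal closed loop", {
  res <- simulate_session(default_speller_layout(), "THE CAT",
                          user = user_model(0, 0), detector = "ideal", seed = 3)
  expect_equal(res$transcripts, "THE CAT")
  res0 <- simulate_session(default_speller_layout(), "THE CAT",
                           user = user_model(0, 0), detector = "ideal",
                           lexicon = NULL, seed = 3)
  expect_lt(res$durations_s, res0$durations_s)
})

test_that("typed text is reconstructible by replaying the click log", {
  lay <- default_speller_layout()
  res <- simulate_session(lay, "GO ON", user = user_model(0.15, 0.04, error_rate = 0.2),
                          detector = "ideal", seed = 12)
  st <- scan_state(lay, lexicon = default_lexicon(), t = 0)
  for (tc in res$log$detections) {
    st$t <- tc
    st <- apply_click(st)
  }
  expect_equal(sub(" +$", "", st$typed_text), res$transcripts[1])
})

test_that("a stub detector's sensitivity is recovered from the event log", {
  res <- simulate_session(default_speller_layout(), rep("THE CAT SAT", 3),
                          user = user_model(0.15, 0.03),
                          detector = detector_stub(0.85, 0.1), seed = 6)
  n <- length(res$log$grasp_onsets)
  phat <- length(res$log$detections) / n
  ci <- 1.96 * sqrt(0.85 * 0.15 / n)
  expect_lt(abs(phat - 0.85), ci + 0.02)
  expect_equal(res$transcripts, rep("THE CAT SAT", 3))
})

test_that("erring users still converge by correcting with deletions", {
  res <- simulate_session(default_speller_layout(), "THE CAT",
                          user = user_model(0.15, 0.03, error_rate = 0.15),
                          detector = "ideal", seed = 8)
  expect_equal(res$transcripts, "THE CAT")
  expect_gt(res$durations_s, 0)
})

test_that("board mode selects cued keys and recovers from wrong rows", {
  lay <- default_board_layout()
  res <- simulate_session(lay, c("WATER", "YES"), user = user_model(0, 0),
                          detector = "ideal", seed = 2)
  expect_equal(res$transcripts, c("WATER", "YES"))
  res2 <- simulate_session(lay, c("DOCTOR", "PAIN"),
                           user = user_model(0.1, 0.05, error_rate = 0.3),
                           detector = "ideal", seed = 9)
  # wrong-row recovery re-cues a key within the selected row, so every
  # transcript is a real key of the board
  expect_true(all(res2$transcripts %in% unlist(lay$rows)))
})

test_that("unreachable characters are reported by name", {
  expect_error(simulate_session(default_speller_layout(), "A7B",
                                user = user_model(0, 0), detector = "ideal",
                                lexicon = NULL, seed = 1),
               "'7' is unreachable")
  expect_error(simulate_session(default_speller_layout(), character(0)),
               "non-empty")
})
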