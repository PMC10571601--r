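#' Switch-scanning grid layout
#'
#' A grid of keys scanned row-by-row then key-by-key within the selected
#' row. Key kinds: `letter`, `SPACE`, `DEL`, `A-DEL`, `ENTER`,
#' `word-autocomplete` and `letter-autocomplete` (the last two are dynamic
#' slots filled from the lexicon at scan time). Dummy pre-selection steps
#' precede index 0 of each row / column scanning cycle.
#'
#' @param rows List of character vectors of key labels.
#' @param kinds List (parallel to `rows`) of key kinds.
#' @param preselect_rows Pre-selection steps before the first row.
#' @param preselect_cols Pre-selection steps before the first key of a row.
#' @param scan_rate_hz Highlight steps per second.
#' @param mode `"speller"` (text entry, errors corrected by deletion) or
#'   `"board"` (cued key selection, wrong-row recovery by re-cueing).
#' @return Object of class `grid_layout`.
#' @export
grid_layout <- function(rows, kinds, preselect_rows = 3, preselect_cols = 1,
                        scan_rate_hz = 1.5, mode = c("speller", "board")) {
  mode <- match.arg(mode)
  if (!length(rows) || !all(lengths(rows) > 0)) {
    stop_input("layout must have non-empty rows")
  }
  if (!identical(lengths(rows), lengths(kinds))) {
    stop_input("rows and kinds must be parallel")
  }
  special <- unlist(kinds)[unlist(kinds) %in% c("DEL", "A-DEL", "ENTER")]
  if (anyDuplicated(special)) stop_input("special keys must be unique")
  structure(list(rows = rows, kinds = kinds,
                 preselect_rows = as.integer(preselect_rows),
                 preselect_cols = as.integer(preselect_cols),
                 scan_rate_hz = scan_rate_hz, mode = mode),
            class = "grid_layout")
}

#' Default sentence-spelling layout
#'
#' A word-suggestion row, a five-row center keyboard prefixed by a
#' letter-suggestion column, and SPACE/DEL/A-DEL/ENTER keys.
#'
#' @param n_word_slots Number of word-autocomplete slots.
#' @param scan_rate_hz Highlight rate (default 1.5/s).
#' @return A [grid_layout()] in speller mode.
#' @export
default_speller_layout <- function(n_word_slots = 3, scan_rate_hz = 1.5) {
  letters5 <- list(c("A", "B", "C", "D", "E", "F"),
                   c("G", "H", "I", "J", "K", "L"),
                   c("M", "N", "O", "P", "Q", "R"),
                   c("S", "T", "U", "V", "W", "X"))
  rows <- c(list(rep("", n_word_slots)),
            lapply(letters5, function(r) c("", r)),
            list(c("", "Y", "Z", "SPACE", "DEL", "A-DEL", "ENTER")))
  kinds <- c(list(rep("word-autocomplete", n_word_slots)),
             lapply(letters5, function(r) c("letter-autocomplete",
                                            rep("letter", length(r)))),
             list(c("letter-autocomplete", "letter", "letter",
                    "SPACE", "DEL", "A-DEL", "ENTER")))
  grid_layout(rows, kinds, scan_rate_hz = scan_rate_hz, mode = "speller")
}

#' Default medical communication board layout
#'
#' @param scan_rate_hz Highlight rate (default 1.5/s).
#' @return A [grid_layout()] in board mode with symbol keys.
#' @export
default_board_layout <- function(scan_rate_hz = 1.5) {
  items <- list(c("YES", "NO", "PAIN", "HELP"),
                c("WATER", "FOOD", "REST", "TOILET"),
                c("HOT", "COLD", "UP", "DOWN"),
                c("DOCTOR", "NURSE", "FAMILY", "THANKS"))
  grid_layout(items, lapply(items, function(r) rep("letter", length(r))),
              scan_rate_hz = scan_rate_hz, mode = "board")
}

#' Small built-in word-frequency lexicon
#'
#' @return Named numeric vector (word -> relative frequency) used by the
#'   autocomplete stub.
#' @export
default_lexicon <- function() {
  c(THE = 1000, BE = 600, TO = 580, OF = 550, AND = 540, A = 530, IN = 500,
    THAT = 400, HAVE = 390, IT = 380, FOR = 370, NOT = 360, ON = 350,
    WITH = 340, HE = 330, AS = 320, YOU = 310, DO = 300, AT = 290,
    THIS = 280, BUT = 270, HIS = 260, BY = 250, FROM = 240, THEY = 230,
    WE = 220, SAY = 210, HER = 200, SHE = 190, OR = 180, WILL = 170,
    MY = 160, ONE = 150, ALL = 140, WOULD = 130, THERE = 120, THEIR = 110,
    WHAT = 100, OUT = 95, ABOUT = 90, WHO = 85, GET = 80, WHICH = 75,
    GO = 70, ME = 65, WHEN = 60, MAKE = 55, CAN = 50, LIKE = 45,
    TIME = 40, JUST = 35, HIM = 30, KNOW = 28, TAKE = 26, PEOPLE = 24,
    INTO = 22, YEAR = 20, YOUR = 18, GOOD = 16, SOME = 14, COULD = 12,
    THEM = 10, SEE = 9, OTHER = 8, THAN = 7, THEN = 6, NOW = 5,
    LOOK = 4, ONLY = 3, COME = 2, OVER = 1)
}

#' Ranked word completions for a prefix
#'
#' Deterministic frequency-weighted prefix lookup (the pluggable stand-in
#' for a language-model completer).
#'
#' @param prefix Current word prefix (may be empty).
#' @param lexicon Named numeric vector, word -> frequency.
#' @param n Maximum number of suggestions.
#' @return Character vector of suggested words, highest frequency first
#'   (ties alphabetical).
#' @export
autocomplete <- function(prefix, lexicon, n = 3) {
  if (!length(lexicon)) stop_input("empty lexicon")
  prefix <- toupper(prefix)
  words <- names(lexicon)
  hit <- if (nzchar(prefix)) startsWith(words, prefix) else rep(TRUE, length(words))
  w <- words[hit]; f <- lexicon[hit]
  w[order(-f, w)][seq_len(min(n, length(w)))]
}

# Ranked next-letter suggestions for the current word prefix.
letter_suggestions <- function(prefix, lexicon, n = 5) {
  prefix <- toupper(prefix)
  words <- names(lexicon)
  hit <- startsWith(words, prefix) & nchar(words) > nchar(prefix)
  if (!any(hit)) return(character(0))
  nxt <- substr(words[hit], nchar(prefix) + 1, nchar(prefix) + 1)
  f <- tapply(lexicon[hit], nxt, sum)
  names(sort(f, decreasing = TRUE))[seq_len(min(n, length(f)))]
}

current_word_prefix <- function(typed) {
  sub("^.* ", "", typed)
}

# Fill dynamic (autocomplete) slots with their current suggestions.
resolve_labels <- function(layout, typed, lexicon) {
  rows <- layout$rows
  if (is.null(lexicon)) return(rows)
  prefix <- current_word_prefix(typed)
  wsl <- autocomplete(prefix, lexicon, n = sum(unlist(layout$kinds) == "word-autocomplete"))
  lsl <- letter_suggestions(prefix, lexicon,
                            n = sum(unlist(layout$kinds) == "letter-autocomplete"))
  wi <- 0; li <- 0
  for (r in seq_along(rows)) {
    for (c in seq_along(rows[[r]])) {
      k <- layout$kinds[[r]][c]
      if (k == "word-autocomplete") {
        wi <- wi + 1
        rows[[r]][c] <- if (wi <= length(wsl)) wsl[wi] else ""
      } else if (k == "letter-autocomplete") {
        li <- li + 1
        rows[[r]][c] <- if (li <= length(lsl)) lsl[li] else ""
      }
    }
  }
  rows
}

#' Initialize a switch-scanning state
#'
#' @param layout A [grid_layout()].
#' @param lexicon Optional word-frequency lexicon for dynamic slots.
#' @param t Session clock at initialization, seconds.
#' @return Object of class `scan_state`.
#' @export
scan_state <- function(layout, lexicon = NULL, t = 0) {
  structure(list(layout = layout, lexicon = lexicon,
                 phase = "row", phase_start = t, t = t,
                 selected_row = NA_integer_, typed_text = "",
                 last_kind = NA_character_, done = FALSE),
            class = "scan_state")
}

n_scan_items <- function(state) {
  if (state$phase == "row") length(state$layout$rows)
  else length(state$layout$rows[[state$selected_row]])
}

n_prescan <- function(state) {
  if (state$phase == "row") state$layout$preselect_rows
  else state$layout$preselect_cols
}

#' Highlighted index at the current scan time
#'
#' Negative values are pre-selection steps; `0 .. n-1` index the rows (row
#' phase) or the keys of the selected row (column phase). The schedule
#' wraps cyclically, pre-selection steps included in every cycle.
#'
#' @param state A [scan_state()].
#' @return Integer highlight index.
#' @export
scan_highlight <- function(state) {
  rate <- state$layout$scan_rate_hz
  pre <- n_prescan(state)
  n <- n_scan_items(state)
  step <- floor((state$t - state$phase_start) * rate + 1e-9) %% (pre + n)
  step - pre
}

#' Advance the scan clock
#'
#' @param state A [scan_state()].
#' @param dt_s Non-negative time increment, seconds.
#' @return Updated state (highlight follows from the elapsed time).
#' @export
advance_scan <- function(state, dt_s) {
  if (dt_s < 0) stop_input("dt_s must be >= 0")
  state$t <- state$t + dt_s
  state
}

#' Apply a click to the scanning state
#'
#' During row scanning a click selects the highlighted row and starts
#' column scanning; during column scanning it activates the highlighted
#' key (letter append, word-completion substitution, DEL, A-DEL, ENTER,
#' SPACE) and restarts row scanning. Clicks landing on a pre-selection
#' step are ignored.
#'
#' @param state A [scan_state()].
#' @return Updated state.
#' @export
apply_click <- function(state) {
  h <- scan_highlight(state)
  if (h < 0) return(state)   # pre-selection: nothing highlighted
  if (state$phase == "row") {
    state$selected_row <- h + 1L
    state$phase <- "col"
    state$phase_start <- state$t
    return(state)
  }
  r <- state$selected_row; c <- h + 1L
  kind <- state$layout$kinds[[r]][c]
  label <- resolve_labels(state$layout, state$typed_text, state$lexicon)[[r]][c]
  typed <- state$typed_text
  if (kind == "letter" && nzchar(label)) {
    typed <- paste0(typed, label)
  } else if (kind == "SPACE") {
    typed <- paste0(typed, " ")
  } else if (kind == "DEL") {
    typed <- substr(typed, 1, max(0, nchar(typed) - 1))
  } else if (kind == "A-DEL") {
    typed <- sub("[^ ]*$", "", sub(" +$", "", typed))
  } else if (kind == "ENTER") {
    state$done <- TRUE
  } else if (kind == "word-autocomplete" && nzchar(label)) {
    typed <- paste0(sub("[^ ]*$", "", typed), label, " ")
  } else if (kind == "letter-autocomplete" && nzchar(label)) {
    typed <- paste0(typed, label)
  }
  state$typed_text <- typed
  state$last_kind <- kind
  state$phase <- "row"
  state$phase_start <- state$t
  state$selected_row <- NA_integer_
  state
}

#' Simulated-user model
#'
#' Stand-in for the human participant: reaction delay after the target
#' becomes highlighted, and a probability of attempting on a wrong
#' highlight.
#'
#' @param reaction_mean_s,reaction_sd_s Gaussian grasp-initiation delay
#'   (truncated at zero), seconds.
#' @param error_rate Probability a given attempt targets a wrong step.
#' @return Object of class `user_model`.
#' @export
user_model <- function(reaction_mean_s = 0.2, reaction_sd_s = 0.05,
                       error_rate = 0) {
  if (reaction_mean_s < 0) stop_input("reaction_mean_s must be >= 0")
  if (error_rate < 0 || error_rate > 1) stop_input("error_rate must be in [0, 1]")
  structure(list(reaction_mean_s = reaction_mean_s,
                 reaction_sd_s = reaction_sd_s, error_rate = error_rate),
            class = "user_model")
}

#' Click-detector stubs for session simulation
#'
#' @param sensitivity Probability an attempted grasp yields a click.
#' @param latency_s Constant attempt-to-click latency, seconds.
#' @return Detector function `(t_attempt) -> click time or NA`.
#' @export
detector_stub <- function(sensitivity = 1, latency_s = 0) {
  force(sensitivity); force(latency_s)
  function(t_attempt) {
    if (stats::runif(1) <= sensitivity) t_attempt + latency_s else NA_real_
  }
}

# Locate a key by predicate on (kind, effective label); first match in
# row-major order, NULL if absent.
find_key <- function(layout, labels, pred) {
  for (r in seq_along(labels)) {
    for (c in seq_along(labels[[r]])) {
      if (pred(layout$kinds[[r]][c], labels[[r]][c])) {
        return(c(row = r, col = c))
      }
    }
  }
  NULL
}

# Greedy plan: word completion when a slot shows the target word, else the
# next needed letter/space; deletion keys when the typed text has diverged.
plan_next_key <- function(state, prompt) {
  layout <- state$layout
  typed <- state$typed_text
  labels <- resolve_labels(layout, state$typed_text, state$lexicon)
  if (sub(" +$", "", typed) == prompt) {
    return(find_key(layout, labels, function(k, l) k == "ENTER"))
  }
  if (!startsWith(prompt, typed)) {
    want <- if (identical(state$last_kind, "word-autocomplete")) "A-DEL" else "DEL"
    pos <- find_key(layout, labels, function(k, l) k == want)
    if (is.null(pos)) pos <- find_key(layout, labels, function(k, l) k == "DEL")
    return(pos)
  }
  nxt <- substr(prompt, nchar(typed) + 1, nchar(typed) + 1)
  if (nxt != " ") {
    # target word = prompt word covering the next position
    rest <- substr(prompt, nchar(typed) + 1, nchar(prompt))
    partial <- current_word_prefix(typed)
    target_word <- paste0(partial, sub(" .*$", "", rest))
    pos <- find_key(layout, labels, function(k, l) {
      k == "word-autocomplete" && identical(l, target_word)
    })
    if (!is.null(pos)) return(pos)
  }
  pos <- if (nxt == " ") {
    find_key(layout, labels, function(k, l) k == "SPACE")
  } else {
    find_key(layout, labels, function(k, l) k == "letter" && identical(l, nxt))
  }
  if (is.null(pos)) stop_input("character '%s' is unreachable in this layout", nxt)
  pos
}

# Next time >= t at which step `target_step` (0-based, pre-steps included)
# of the current phase cycle begins.
next_step_time <- function(state, target_step) {
  rate <- state$layout$scan_rate_hz
  period <- n_prescan(state) + n_scan_items(state)
  k <- ceiling(((state$t - state$phase_start) * rate - target_step - 1e-9) / period)
  state$phase_start + (max(k, 0) * period + target_step) / rate
}

#' Simulate closed-loop switch-scanning sessions
#'
#' Drives the scanning state machine with a modelled user and a pluggable
#' click detector. In speller mode the user greedily plans the key
#' sequence for each prompted sentence (word completion when offered, else
#' the next letter), times grasp attempts to the target highlights with
#' reaction jitter, and corrects errors via DEL/A-DEL. In board mode each
#' prompt is a cued key; a wrong-row selection re-cues a key within that
#' row, per the board protocol.
#'
#' @param layout A [grid_layout()].
#' @param prompts Character vector: sentences (speller) or key labels
#'   (board).
#' @param user A [user_model()].
#' @param detector `"ideal"`, or a function from [detector_stub()].
#' @param lexicon Word-frequency lexicon for autocomplete slots.
#' @param seed Seed for user/detector randomness.
#' @param max_time_s Per-prompt simulation cap, seconds.
#' @return List with `transcripts`, `durations_s`, per-prompt `scores`
#'   (speller mode), the assigned [click_event_log()] (`log`) and
#'   `total_duration_s`.
#' @export
simulate_session <- function(layout, prompts, user = user_model(),
                             detector = "ideal",
                             lexicon = default_lexicon(), seed = 1,
                             max_time_s = 1800) {
  if (!length(prompts)) stop_input("prompts must be non-empty")
  if (identical(detector, "ideal")) detector <- detector_stub(1, 0)
  prompts <- toupper(prompts)
  attempts <- numeric(0); clicks <- numeric(0)
  transcripts <- character(length(prompts))
  durations <- numeric(length(prompts))
  t_global <- 0
  with_seed(derive_seed(seed, 909), {
    for (pi in seq_along(prompts)) {
      prompt <- prompts[pi]
      state <- scan_state(layout, lexicon, t = t_global)
      t_start <- t_global
      board_target <- if (layout$mode == "board") prompt else NULL
      while (!state$done) {
        if (state$t - t_start > max_time_s) {
          warning(sprintf("prompt %d timed out after %.0f s", pi, max_time_s))
          break
        }
        pos <- if (layout$mode == "board") {
          if (state$phase == "row") {
            r <- which(vapply(layout$rows, function(rr) board_target %in% rr, TRUE))[1]
            c(row = r, col = match(board_target, layout$rows[[r]]))
          } else {
            c(row = state$selected_row,
              col = match(board_target, layout$rows[[state$selected_row]]))
          }
        } else {
          plan_next_key(state, prompt)
        }
        target_idx <- if (state$phase == "row") pos["row"] - 1L else pos["col"] - 1L
        if (layout$mode == "board" && state$phase == "col" && is.na(target_idx)) {
          # cued key not in the selected row: re-cue to a key within it
          board_target <- layout$rows[[state$selected_row]][1]
          target_idx <- 0L
        }
        step <- n_prescan(state) + target_idx
        if (user$error_rate > 0 && stats::runif(1) < user$error_rate) {
          wrong <- setdiff(seq_len(n_scan_items(state)) - 1L, target_idx)
          step <- n_prescan(state) + sample(wrong, 1)
        }
        t_high <- next_step_time(state, step)
        reaction <- max(0, stats::rnorm(1, user$reaction_mean_s,
                                        user$reaction_sd_s))
        t_attempt <- t_high + reaction
        attempts <- c(attempts, t_attempt)
        t_click <- detector(t_attempt)
        if (is.na(t_click)) {
          state$t <- t_attempt      # missed: wait for the next cycle
          next
        }
        clicks <- c(clicks, t_click)
        state$t <- t_click
        state <- apply_click(state)
        if (layout$mode == "board" && state$phase == "row" &&
            !is.na(state$last_kind) && state$last_kind == "letter") {
          state$done <- TRUE   # board: one key activation completes the cue
        }
      }
      transcripts[pi] <- sub(" +$", "", state$typed_text)
      durations[pi] <- state$t - t_start
      t_global <- state$t
    }
  })
  log <- click_event_log(attempts, clicks, clicks, max(t_global, 1e-9))
  log <- assign_events(log)
  scores <- if (layout$mode == "speller") {
    lapply(seq_along(prompts), function(i) {
      score_spelling(transcripts[i], prompts[i], max(durations[i], 1e-9))
    })
  } else NULL
  list(transcripts = transcripts, durations_s = durations, scores = scores,
       log = log, total_duration_s = t_global)
}
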