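#' Generate a roving-oddball stimulus sequence
#'
#' Builds an ordered sequence of tone events organized in trains of repeated
#' fundamental frequency. Train lengths are drawn uniformly from
#' `train_range`, each new train's F0 is drawn uniformly from `f0_grid`
#' excluding the current F0 (immediate repeats are barred; earlier F0s may
#' recur), and the last train is truncated so the sequence has exactly
#' `n_sounds` events. Roles are unset until [label_events()] is applied.
#'
#' @param n_sounds Total number of events (default 600, one ~6 min block at
#'   the default 600 ms inter-onset interval).
#' @param f0_grid Allowed fundamental frequencies in Hz; needs at least two
#'   members so the F0 can change.
#' @param train_range Integer `c(min, max)` train length (default 4 to 7).
#' @param ioi Inter-onset interval in seconds (metadata only).
#' @return Object of class `roving_sequence`: list with `events` (data frame
#'   `index`, `train_id`, `within_train_pos`, `f0`, `role`), `f0_grid`,
#'   `train_range`, `n_sounds`, `ioi`.
#' @export
#' @examples
#' set.seed(1)
#' seq6 <- generate_roving_sequence(60)
#' table(label_events(seq6)$events$role)
generate_roving_sequence <- function(n_sounds = 600,
                                     f0_grid = seq(200, 500, by = 50),
                                     train_range = c(4L, 7L),
                                     ioi = 0.600) {
  if (length(f0_grid) < 2L)
    stop("`f0_grid` needs at least two members so the F0 can change")
  stopifnot(n_sounds >= 1, train_range[1] >= 1, train_range[2] >= train_range[1])
  len_choices <- seq.int(train_range[1], train_range[2])
  lens <- integer(0)
  total <- 0L
  while (total < n_sounds) {
    l <- if (length(len_choices) == 1L) len_choices else sample(len_choices, 1L)
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - n_sounds)
  lens <- lens[lens > 0L]

  f0s <- numeric(length(lens))
  f0s[1] <- sample(f0_grid, 1L)
  for (i in seq_along(lens)[-1]) {
    choices <- f0_grid[f0_grid != f0s[i - 1]]
    f0s[i] <- if (length(choices) == 1L) choices else sample(choices, 1L)
  }

  events <- data.frame(
    index = seq_len(n_sounds),
    train_id = rep(seq_along(lens), lens),
    within_train_pos = unlist(lapply(lens, seq_len), use.names = FALSE),
    f0 = rep(f0s, lens),
    role = NA_character_
  )
  structure(list(events = events, f0_grid = f0_grid,
                 train_range = as.integer(train_range),
                 n_sounds = as.integer(n_sounds), ioi = ioi),
            class = "roving_sequence")
}

#' Assign deviant/standard/excluded roles to a roving sequence
#'
#' The first event of every train after the first is a deviant (the first
#' train's opening tone has no preceding context). The two events
#' immediately following each deviant position are excluded, as are the
#' first five events of the whole sequence; the first-five rule takes
#' precedence over any deviant label in those positions. Every remaining
#' event is a standard. The three roles partition the sequence.
#'
#' @param sequence A `roving_sequence`.
#' @return The sequence with `events$role` filled in.
#' @export
label_events <- function(sequence) {
  stopifnot(inherits(sequence, "roving_sequence"))
  ev <- sequence$events
  n <- nrow(ev)
  deviant_pos <- which(ev$within_train_pos == 1L & ev$train_id > 1L)
  role <- rep("standard", n)
  role[deviant_pos] <- "deviant"
  # two sounds after each (candidate) deviant carry over deviant response
  post <- unique(c(deviant_pos + 1L, deviant_pos + 2L))
  post <- post[post <= n & !(post %in% deviant_pos)]
  role[post] <- "excluded"
  role[seq_len(min(5L, n))] <- "excluded"
  ev$role <- role
  sequence$events <- ev
  sequence
}
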