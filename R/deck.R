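#' @keywords internal
"_PACKAGE"

#' @useDynLib schemabg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif sd cor pt setNames quantile
#' @importFrom utils write.csv
NULL

# Feature levels, in target order: feature k of dimension d belongs to target k.
.colours <- c("red", "green", "yellow", "blue")
.shapes  <- c("triangle", "star", "cross", "circle")
.rules   <- c("colour", "shape", "number")

#' The four fixed target cards
#'
#' Target card k shows k copies of one shape in one colour: (1 red triangle),
#' (2 green stars), (3 yellow crosses), (4 blue circles). Every stimulus card
#' is matched against these four targets on colour, shape and number.
#'
#' @return A data frame with columns `target` (1--4), `colour`, `shape`,
#'   `number`.
#' @export
wcst_targets <- function() {
  data.frame(
    target = 1:4,
    colour = .colours,
    shape  = .shapes,
    number = 1:4,
    stringsAsFactors = FALSE
  )
}

#' Build a stimulus card
#'
#' @param colour One of `"red"`, `"green"`, `"yellow"`, `"blue"`.
#' @param shape One of `"triangle"`, `"star"`, `"cross"`, `"circle"`.
#' @param number Integer 1--4.
#'
#' @return A one-row data frame with the card's features and the target index
#'   it points to under each sorting rule (`t_colour`, `t_shape`, `t_number`).
#' @export
wcst_card <- function(colour, shape, number) {
  colour <- match.arg(colour, .colours)
  shape <- match.arg(shape, .shapes)
  stopifnot(number %in% 1:4)
  data.frame(
    colour = colour, shape = shape, number = as.integer(number),
    t_colour = match(colour, .colours),
    t_shape  = match(shape, .shapes),
    t_number = as.integer(number),
    stringsAsFactors = FALSE
  )
}

#' The unambiguous 24-card deck
#'
#' Of the 64 colour x shape x number combinations, only cards whose three
#' feature dimensions point to three pairwise-distinct targets are kept, so
#' every card shares exactly one feature with each of three targets and no
#' feature with the fourth. A response to any matching target then identifies
#' the sorting rule uniquely, which is what makes the deck unambiguous.
#'
#' @return A 24-row data frame in the format of [wcst_card()].
#' @export
wcst_deck <- function() {
  grid <- expand.grid(colour = 1:4, shape = 1:4, number = 1:4)
  keep <- with(grid, colour != shape & colour != number & shape != number)
  grid <- grid[keep, ]
  deck <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    wcst_card(.colours[grid$colour[i]], .shapes[grid$shape[i]], grid$number[i])))
  rownames(deck) <- NULL
  deck
}

#' Build a trial sequence from shuffled deck copies
#'
#' Concatenates independently shuffled copies of the full 24-card deck and
#' truncates to `n_trials`, so no card repeats before the whole deck has been
#' seen (avoiding the long duplicate runs i.i.d. sampling would produce).
#'
#' @param n_trials Number of trials (>= 1).
#' @param seed Optional integer; when supplied the sequence is drawn from
#'   `seed` without disturbing the caller's RNG state. When `NULL` the current
#'   RNG stream is used (this is what [run_session()] does internally).
#'
#' @return A data frame of `n_trials` cards with a `trial` column.
#' @export
build_trial_sequence <- function(n_trials, seed = NULL) {
  if (!is.numeric(n_trials) || length(n_trials) != 1L || n_trials < 1)
    stop("`n_trials` must be a single integer >= 1")
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  deck <- wcst_deck()
  n_copies <- ceiling(n_trials / nrow(deck))
  idx <- unlist(lapply(seq_len(n_copies), function(i) sample.int(nrow(deck))))
  out <- deck[idx[seq_len(n_trials)], ]
  out$trial <- seq_len(n_trials)
  rownames(out) <- NULL
  out
}

#' Which targets does a card match?
#'
#' @param card A one-row data frame from [wcst_card()] / [wcst_deck()].
#' @return Integer vector of length 4; entry i is 1 iff the card shares at
#'   least one feature with target i. Deck cards match exactly three targets.
#' @export
stimulus_match_vector <- function(card) {
  v <- integer(4)
  v[unique(c(card$t_colour, card$t_shape, card$t_number))] <- 1L
  v
}

#' Target a sorting rule maps a card onto
#'
#' @param card A card.
#' @param rule `"colour"`, `"shape"` or `"number"`.
#' @return The target index (1--4) the card goes to under `rule`.
#' @export
rule_target <- function(card, rule) {
  rule <- match.arg(rule, .rules)
  switch(rule, colour = card$t_colour, shape = card$t_shape, number = card$t_number)
}

#' Sorting rule implied by a response
#'
#' For deck cards each matching target corresponds to exactly one feature
#' dimension, so the applied rule can be scored from the response alone.
#'
#' @param card A card.
#' @param response Target index 1--4.
#' @return `"colour"`, `"shape"`, `"number"`, or `NA_character_` if the chosen
#'   target shares no feature with the card.
#' @export
applied_rule <- function(card, response) {
  stopifnot(response %in% 1:4)
  hits <- .rules[c(card$t_colour, card$t_shape, card$t_number) == response]
  if (length(hits) == 0L) NA_character_ else hits[1L]
}
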