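#' Built-in psychometric instrument registry
#'
#' Specifications for the biweekly survey battery: number of items, item
#' response scale, reverse-scored items, and short item codes where the
#' analysis reports item-level comparisons (PQ-16 and the 9-item PSQI
#' frequency variant).
#'
#' Scoring conventions:
#' \describe{
#'   \item{PHQ9}{9 items, 0--3, summed (max 27).}
#'   \item{GAD7}{7 items, 0--3, summed (max 21).}
#'   \item{PSS}{10 items, 0--4, items 4, 5, 7, 8 reverse-scored, summed
#'     (max 40). Scores of 14 or more indicate at least moderate stress.}
#'   \item{UCLA}{UCLA Loneliness scale, 20 items, 1--4, summed (max 80).}
#'   \item{PQ16}{Prodromal Questionnaire, ordinal variant: 16 items each
#'     0--3, summed (max 48).}
#'   \item{PSQI9}{Sleep-quality battery, shortened 9-question frequency
#'     adaptation: 9 items each 0--3, summed (max 27).}
#'   \item{DWAI}{Digital Working Alliance Inventory, 6 items, 1--7, summed
#'     (max 42).}
#' }
#'
#' @param instrument_id optional single instrument id; if given, return that
#'   spec only.
#' @return a named list of instrument specs (or a single spec), each a list
#'   with `instrument_id`, `n_items`, `scale_min`, `scale_max`,
#'   `reverse_items`, `item_codes`, `max_score`.
#' @export
#' @examples
#' instrument_registry("PSS")$reverse_items
instrument_registry <- function(instrument_id = NULL) {
  reg <- list(
    PHQ9  = make_instrument("PHQ9", 9, 0, 3),
    GAD7  = make_instrument("GAD7", 7, 0, 3),
    PSS   = make_instrument("PSS", 10, 0, 4, reverse_items = c(4L, 5L, 7L, 8L)),
    UCLA  = make_instrument("UCLA", 20, 1, 4),
    PQ16  = make_instrument("PQ16", 16, 0, 3, item_codes = pq16_item_codes()),
    PSQI9 = make_instrument("PSQI9", 9, 0, 3, item_codes = psqi9_item_codes()),
    DWAI  = make_instrument("DWAI", 6, 1, 7)
  )
  if (is.null(instrument_id)) return(reg)
  if (!instrument_id %in% names(reg)) {
    stop("unknown instrument id: ", instrument_id)
  }
  reg[[instrument_id]]
}

make_instrument <- function(id, n_items, scale_min, scale_max,
                            reverse_items = integer(0), item_codes = NULL) {
  stopifnot(scale_max > scale_min, n_items >= 1,
            all(reverse_items >= 1), all(reverse_items <= n_items))
  if (is.null(item_codes)) {
    item_codes <- paste0(id, "_", seq_len(n_items))
  }
  stopifnot(length(item_codes) == n_items)
  structure(list(
    instrument_id = id,
    n_items = n_items,
    scale_min = scale_min,
    scale_max = scale_max,
    reverse_items = as.integer(reverse_items),
    item_codes = item_codes,
    max_score = n_items * scale_max
  ), class = "instrument_spec")
}

pq16_item_codes <- function() {
  c("Uninterested", "Deja Vu", "Smell/Taste", "Sounds", "Reality",
    "Hallucination", "Meeting anxiety", "Seeing things", "Thoughts",
    "Meaning", "Control", "Distracting sounds", "Voices", "Paranoia",
    "Nearby", "Body")
}

psqi9_item_codes <- function() {
  c("Restless", "Waking up", "Breathing", "Cough/Snore", "Hot",
    "Bad dreams", "Pain", "Tired", "Mood")
}

#' Score one instrument administration
#'
#' Sums item responses after reversing the instrument's reverse-scored items
#' (reversed value = scale_max - response + scale_min).
#'
#' @param instrument an instrument spec from [instrument_registry()], or an
#'   instrument id string.
#' @param responses integer vector of item responses, length `n_items`, each
#'   on the instrument scale.
#' @return integer raw score.
#' @export
#' @examples
#' score_instrument("PSS", rep(0, 10))  # 16: four reversed items contribute 4 each
score_instrument <- function(instrument, responses) {
  spec <- as_instrument(instrument)
  if (length(responses) != spec$n_items) {
    stop(spec$instrument_id, ": expected ", spec$n_items, " responses, got ",
         length(responses))
  }
  bad <- which(is.na(responses) | responses < spec$scale_min |
                 responses > spec$scale_max | responses != round(responses))
  if (length(bad)) {
    stop(spec$instrument_id, ": invalid response for item(s) ",
         paste(bad, collapse = ", "))
  }
  r <- as.numeric(responses)
  if (length(spec$reverse_items)) {
    r[spec$reverse_items] <- spec$scale_max - r[spec$reverse_items] + spec$scale_min
  }
  sum(r)
}

#' Reverse-score the reverse-keyed items of a response vector
#'
#' Applying this twice restores the original vector.
#'
#' @inheritParams score_instrument
#' @return numeric vector with reverse-keyed items flipped.
#' @export
reverse_items <- function(instrument, responses) {
  spec <- as_instrument(instrument)
  r <- as.numeric(responses)
  if (length(spec$reverse_items)) {
    r[spec$reverse_items] <- spec$scale_max - r[spec$reverse_items] + spec$scale_min
  }
  r
}

#' Normalize a raw score to [0, 1]
#'
#' Raw score divided by the instrument's maximum possible score, so
#' instruments of different lengths are comparable on one scale.
#'
#' @inheritParams score_instrument
#' @param raw_score integer raw score.
#' @export
normalize_score <- function(instrument, raw_score) {
  spec <- as_instrument(instrument)
  raw_score / spec$max_score
}

#' Perceived-stress eligibility flag
#'
#' Participants qualify when their enrollment PSS raw score meets the
#' moderate-stress threshold.
#'
#' @param raw_score PSS raw score (0--40).
#' @param threshold eligibility threshold, default 14.
#' @return logical.
#' @export
eligibility_pss <- function(raw_score, threshold = 14) {
  stopifnot(is.numeric(raw_score))
  !is.na(raw_score) & raw_score >= threshold
}

as_instrument <- function(instrument) {
  if (inherits(instrument, "instrument_spec")) return(instrument)
  instrument_registry(instrument)
}

#' Score a long-format table of survey administrations
#'
#' @param administrations data.frame in long format with columns
#'   `participant_id`, `instrument_id`, `ts`, `item_index`, `response`; one
#'   row per item per administration (an administration is a unique
#'   participant / instrument / ts triple).
#' @return data.frame with one row per administration: `participant_id`,
#'   `instrument_id`, `ts`, `raw_score`, `normalized_score`.
#' @export
score_administrations <- function(administrations) {
  need <- c("participant_id", "instrument_id", "ts", "item_index", "response")
  stopifnot(all(need %in% names(administrations)))
  key <- interaction(administrations$participant_id,
                     administrations$instrument_id,
                     administrations$ts, drop = TRUE)
  parts <- split(administrations, key)
  rows <- lapply(parts, function(a) {
    a <- a[order(a$item_index), ]
    raw <- score_instrument(a$instrument_id[1], a$response)
    data.frame(participant_id = a$participant_id[1],
               instrument_id = a$instrument_id[1],
               ts = a$ts[1],
               raw_score = raw,
               normalized_score = normalize_score(a$instrument_id[1], raw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$instrument_id, out$ts), ]
}

#' Per-participant mean normalized score
#'
#' Arithmetic mean of normalized scores over the administrations each
#' participant completed; participants with no completed administration of
#' an instrument are absent from the result (missing, not zero).
#'
#' @param scored output of [score_administrations()].
#' @return data.frame `participant_id`, `instrument_id`, `mean_normalized`,
#'   `n_administrations`.
#' @export
participant_mean <- function(scored) {
  stopifnot(nrow(scored) >= 1)
  agg <- aggregate(normalized_score ~ participant_id + instrument_id,
                   data = scored, FUN = mean)
  n <- aggregate(normalized_score ~ participant_id + instrument_id,
                 data = scored, FUN = length)
  out <- merge(agg, n, by = c("participant_id", "instrument_id"),
               suffixes = c("", "_n"))
  names(out)[names(out) == "normalized_score"] <- "mean_normalized"
  names(out)[names(out) == "normalized_score_n"] <- "n_administrations"
  out[order(out$participant_id, out$instrument_id), ]
}

#' Per-participant per-item mean responses
#'
#' Item-level means across administrations, used for question-level group
#' comparisons; item codes come from the instrument registry.
#'
#' @param administrations long-format administrations (see
#'   [score_administrations()]).
#' @param instrument instrument id or spec.
#' @return data.frame `participant_id`, `item_index`, `item_code`,
#'   `mean_response`.
#' @export
item_matrix <- function(administrations, instrument) {
  spec <- as_instrument(instrument)
  a <- administrations[administrations$instrument_id == spec$instrument_id, ]
  if (!nrow(a)) {
    return(data.frame(participant_id = character(0), item_index = integer(0),
                      item_code = character(0), mean_response = numeric(0)))
  }
  agg <- aggregate(response ~ participant_id + item_index, data = a, FUN = mean)
  agg$item_code <- spec$item_codes[agg$item_index]
  names(agg)[names(agg) == "response"] <- "mean_response"
  agg[order(agg$participant_id, agg$item_index),
      c("participant_id", "item_index", "item_code", "mean_response")]
}
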