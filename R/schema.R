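#' Phonological annotation schema
#'
#' The fixed set of twelve annotation slots a sign entry may carry.
#' Handshape and location are annotated separately for the dominant and
#' non-dominant hand at the beginning and end of the sign; movement covers
#' local movement, path movement, movement axis, and the behavior of the
#' non-dominant hand. One-handed signs simply leave the non-dominant slots
#' empty.
#'
#' @format Character vector of slot names.
#' @export
slot_schema <- c(
  "hs_dom_begin", "hs_dom_end", "hs_nondom_begin", "hs_nondom_end",
  "loc_dom_begin", "loc_dom_end", "loc_nondom_begin", "loc_nondom_end",
  "mov_local", "mov_path", "mov_axis", "mov_nondom_behavior"
)

.scope_slot_map <- list(
  handshape = slot_schema[1:4],
  location  = slot_schema[5:8],
  movement  = slot_schema[9:12],
  entire    = slot_schema
)

#' Phonological parameter scopes
#'
#' A parameter scope names the subset of annotation slots that enter a
#' phonological vector space: `"handshape"`, `"location"`, `"movement"`,
#' or `"entire"` (all twelve slots concatenated).
#'
#' @param name One of `"handshape"`, `"location"`, `"movement"`, `"entire"`.
#' @return A list with elements `name` and `slots`.
#' @examples
#' parameter_scope("handshape")$slots
#' @export
parameter_scope <- function(name = c("handshape", "location", "movement",
                                     "entire")) {
  name <- match.arg(name)
  structure(list(name = name, slots = .scope_slot_map[[name]]),
            class = "parameter_scope")
}

#' @rdname parameter_scope
#' @export
scope_names <- function() names(.scope_slot_map)

# Resolve a scope given either a name or a parameter_scope object.
as_scope <- function(scope) {
  if (inherits(scope, "parameter_scope")) return(scope)
  parameter_scope(scope)
}

#' Normalize a gloss to its embedding-token form
#'
#' Lowercases, strips surrounding whitespace, and replaces internal
#' whitespace runs with a single hyphen so that multi-word glosses can be
#' matched against hyphenated embedding tokens.
#'
#' @param gloss Character vector of raw gloss labels.
#' @return Character vector of normalized glosses.
#' @examples
#' normalize_gloss("  Ice Cream ")
#' @export
normalize_gloss <- function(gloss) {
  g <- tolower(trimws(as.character(gloss)))
  gsub("\\s+", "-", g)
}
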