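#' Directional DBS lead geometry
#'
#' Construct the standard eight-contact directional lead layout: two ring
#' contacts at the most ventral and most dorsal levels (ids 1 and 8, levels 1
#' and 4) and two segmented levels in between, each split into three contacts
#' spaced 120 degrees apart (level 2: ids 2/3/4; level 3: ids 5/6/7).
#' Segment angles are abstract labels (0/120/240 degrees): the analysis only
#' uses relative direction, never the physical orientation of the lead in the
#' skull. Contacts at the same angle on levels 2 and 3 are "aligned".
#'
#' @return An object of class `directional_lead`: a list with `contacts`
#'   (data.frame with columns `id`, `level`, `angle_deg`, `is_segmented`;
#'   `angle_deg` is `NA` for ring contacts) and `segmented_ids`.
#' @examples
#' lead <- directional_lead()
#' lead$segmented_ids
#' @export
directional_lead <- function() {
  contacts <- data.frame(
    id = 1:8,
    level = c(1L, 2L, 2L, 2L, 3L, 3L, 3L, 4L),
    angle_deg = c(NA, 0, 120, 240, 0, 120, 240, NA),
    is_segmented = c(FALSE, rep(TRUE, 6L), FALSE)
  )
  obj <- structure(list(contacts = contacts, segmented_ids = 2:7),
                   class = "directional_lead")
  validate_lead(obj)
  obj
}

validate_lead <- function(lead) {
  con <- lead$contacts
  if (sum(con$is_segmented) != 6L || sum(!con$is_segmented) != 2L)
    stop("a directional lead has exactly 6 segmented and 2 ring contacts")
  for (lev in c(2L, 3L)) {
    ang <- sort(con$angle_deg[con$level == lev & con$is_segmented])
    if (!identical(ang, c(0, 120, 240)))
      stop("segmented level ", lev, " must carry angles {0, 120, 240}")
  }
  invisible(lead)
}

#' @export
print.directional_lead <- function(x, ...) {
  cat("Directional DBS lead: 8 contacts, 4 levels\n")
  cat("  rings:", paste(x$contacts$id[!x$contacts$is_segmented], collapse = ", "),
      " segmented:", paste(x$segmented_ids, collapse = ", "), "\n")
  print(x$contacts, row.names = FALSE)
  invisible(x)
}

#' Angular distance between two segmented contacts
#'
#' Shortest angular separation, in degrees, between two segmented contacts of
#' a directional lead. This is a metric on the three segment angles; its
#' maximum on a 120-degree-spaced lead is 120.
#'
#' @param lead A [directional_lead()].
#' @param a,b Contact ids (must be segmented contacts).
#' @return Distance in degrees, in \[0, 180\].
#' @examples
#' lead <- directional_lead()
#' angular_distance(lead, 2, 4)  # 0 vs 240 degrees -> 120
#' @export
angular_distance <- function(lead, a, b) {
  con <- lead$contacts
  for (id in c(a, b)) {
    i <- match(id, con$id)
    if (is.na(i)) stop("unknown contact id: ", id)
    if (!con$is_segmented[i])
      stop("angular_distance is defined for segmented contacts only; contact ",
           id, " is a ring")
  }
  ang_dist_deg(con$angle_deg[match(a, con$id)], con$angle_deg[match(b, con$id)])
}

# circular distance for arbitrary angles (used by the simulator's source)
ang_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Aligned contact pairs
#'
#' The six segmented contacts partition into three pairs of contacts facing
#' the same direction on adjacent levels (e.g. contacts 2 and 5 at 0 degrees).
#'
#' @param lead A [directional_lead()].
#' @return data.frame with columns `angle_deg`, `level2_id`, `level3_id`.
#' @export
aligned_pairs <- function(lead) {
  con <- lead$contacts[lead$contacts$is_segmented, ]
  l2 <- con[con$level == 2L, ]
  l3 <- con[con$level == 3L, ]
  l3 <- l3[match(l2$angle_deg, l3$angle_deg), ]
  data.frame(angle_deg = l2$angle_deg, level2_id = l2$id, level3_id = l3$id)
}

#' Serialize / restore a lead description as JSON
#'
#' @param lead A [directional_lead()].
#' @param path File path; for `lead_to_json` with `path = NULL` the JSON
#'   string is returned instead of written.
#' @return `lead_to_json`: the path (or JSON string, invisibly the lead);
#'   `lead_from_json`: a `directional_lead` object.
#' @export
lead_to_json <- function(lead, path = NULL) {
  txt <- jsonlite::toJSON(lead$contacts, dataframe = "rows", pretty = TRUE,
                          na = "null")
  if (is.null(path)) return(as.character(txt))
  writeLines(txt, path)
  invisible(path)
}

#' @rdname lead_to_json
#' @export
lead_from_json <- function(path) {
  con <- jsonlite::fromJSON(path)
  con$angle_deg <- as.numeric(con$angle_deg)
  con <- con[order(con$id), c("id", "level", "angle_deg", "is_segmented")]
  rownames(con) <- NULL
  con$id <- as.integer(con$id); con$level <- as.integer(con$level)
  obj <- structure(list(contacts = con,
                        segmented_ids = con$id[con$is_segmented]),
                   class = "directional_lead")
  validate_lead(obj)
  obj
}
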