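#' The 13 canonical stereo-orientation templates
#'
#' Enumerates the 13 line directions through the center of a 3x3x3 voxel
#' neighborhood. Each template is a centered antipodal triple
#' \{-u, 0, +u\} where `u` is an offset vector with components in
#' \{-1, 0, 1\}. Identifying `u` with `-u` (a line has no sign), the 26
#' non-center neighbors pair up into exactly 13 directions: 3 along the
#' coordinate axes, 6 along face diagonals and 4 along body diagonals.
#'
#' The representative direction stored for each template is the
#' lexicographically larger of \{u, -u\} (compared componentwise x, then y,
#' then z), so every id is unique and reproducible. Ids are assigned in a
#' fixed order: axis directions first, then face diagonals, then body
#' diagonals, each class sorted in decreasing lexicographic order of
#' `(ux, uy, uz)`.
#'
#' @return A data frame with 13 rows and columns `id` (integer 1..13),
#'   `class` (`"axis"`, `"face"` or `"body"`), and integer direction
#'   components `ux`, `uy`, `uz`.
#' @examples
#' tpl <- orientation_templates()
#' table(tpl$class)   # 3 axis, 6 face, 4 body
#' @export
orientation_templates <- function() {
  .avs_env$templates
}

## canonical sign: keep u if it is lexicographically larger than -u
.canonical_direction <- function(u) {
  nz <- which(u != 0)[1]
  if (u[nz] < 0) -u else u
}

.build_templates <- function() {
  offs <- as.matrix(expand.grid(ux = -1:1, uy = -1:1, uz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  can <- t(apply(offs, 1, .canonical_direction))
  can <- unique(can)
  cls <- rowSums(abs(can))
  ## decreasing lexicographic order within each class
  ord <- order(cls, -can[, 1], -can[, 2], -can[, 3])
  can <- can[ord, , drop = FALSE]
  cls <- cls[ord]
  data.frame(
    id = seq_len(nrow(can)),
    class = c("axis", "face", "body")[cls],
    ux = as.integer(can[, 1]),
    uy = as.integer(can[, 2]),
    uz = as.integer(can[, 3])
  )
}

## 13 x 3 integer matrix of representative directions, row o = template o
template_directions <- function() {
  tpl <- orientation_templates()
  as.matrix(tpl[, c("ux", "uy", "uz")])
}

#' Map a template id to its canonical direction vector
#'
#' @param id Integer template id in 1..13.
#' @return Integer vector of length 3.
#' @export
template_direction <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:13)
  as.integer(template_directions()[id, ])
}

#' Find the template id of a direction vector
#'
#' The direction is canonicalized (sign-normalized) first, so `u` and `-u`
#' map to the same id.
#'
#' @param u Integer vector of length 3 with components in -1..1, not all zero.
#' @return Integer template id in 1..13.
#' @export
direction_id <- function(u) {
  u <- as.integer(u)
  stopifnot(length(u) == 3, all(u %in% -1:1), any(u != 0))
  cu <- .canonical_direction(u)
  U <- template_directions()
  which(U[, 1] == cu[1] & U[, 2] == cu[2] & U[, 3] == cu[3])
}

#' Member offsets of a template
#'
#' @param id Integer template id in 1..13.
#' @return A 3 x 3 integer matrix with rows `-u`, `0`, `+u`.
#' @export
template_offsets <- function(id) {
  u <- template_direction(id)
  rbind(-u, c(0L, 0L, 0L), u)
}

#' v-indices of a template's member offsets
#'
#' Offsets within a 3x3x3 neighborhood are addressed by the fixed v-index
#' bijection `v = 14 + dx + 3*dy + 9*dz` for `(dx, dy, dz)` in
#' \{-1, 0, 1\}^3 (x fastest, 1-based; the center is v14).
#'
#' @param id Integer template id in 1..13.
#' @return Integer vector of length 3: the v-indices of `-u`, the center,
#'   and `+u`.
#' @export
template_vindices <- function(id) {
  offs <- template_offsets(id)
  as.integer(14L + offs[, 1] + 3L * offs[, 2] + 9L * offs[, 3])
}

#' Export the template table as JSON
#'
#' Writes the 13 templates (id, class, direction, member offsets) to a JSON
#' file for documentation or cross-implementation comparison.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_templates_json <- function(path) {
  tpl <- orientation_templates()
  recs <- lapply(seq_len(nrow(tpl)), function(i) {
    list(
      id = tpl$id[i],
      class = tpl$class[i],
      direction = c(tpl$ux[i], tpl$uy[i], tpl$uz[i]),
      member_offsets = unname(apply(template_offsets(tpl$id[i]), 1, identity,
                                    simplify = FALSE))
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.avs_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .avs_env$templates <- .build_templates()
}
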