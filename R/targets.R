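#' Canonical synaptic targets and their roles
#'
#' The analysis distinguishes three punctum roles: the anchor marker
#' (synapsin1) that defines candidate synapses, presynaptic markers, and
#' postsynaptic/cytoskeletal markers. The role decides which overlap rule a
#' punctum must meet to be assigned to a synapse (presynaptic: at least 50%
#' of its area on the anchor; postsynaptic: at least 6.25%).
#'
#' @return A data.frame with columns `target` (canonical name) and `role`
#'   (`"anchor"`, `"presynaptic"`, `"postsynaptic"` or `"structural"` for the
#'   MAP2/DAPI reference channels that are never treated as puncta).
#' @export
target_roles <- function() {
  data.frame(
    target = c("Synapsin1", "vGlut1", "vGAT", "Bassoon",
               "PSD95", "SHANK3", "Homer1bc", "NR2B", "Gephyrin",
               "Actin", "Cortactin", "MAP2", "DAPI"),
    role = c("anchor", "presynaptic", "presynaptic", "presynaptic",
             "postsynaptic", "postsynaptic", "postsynaptic", "postsynaptic",
             "postsynaptic", "postsynaptic", "postsynaptic",
             "structural", "structural"),
    stringsAsFactors = FALSE
  )
}

#' @rdname target_roles
#' @export
synaptic_targets <- function() {
  tr <- target_roles()
  tr$target[tr$role != "structural"]
}

#' Look up the role of a target
#' @param target character vector of canonical target names.
#' @return character vector of roles.
#' @export
role_of <- function(target) {
  tr <- target_roles()
  idx <- match(target, tr$target)
  if (anyNA(idx)) {
    stop("unknown target(s): ", paste(target[is.na(idx)], collapse = ", "))
  }
  tr$role[idx]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
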