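#' Default domain-role map
#'
#' Maps the tracked architecture roles to InterPro accessions. The NB-ARC
#' role N is IPR002182 and the four leucine-rich-repeat roles L1-L4 are
#' IPR001611, IPR011713, IPR013210 and IPR025875. The coiled-coil (C) and
#' TIR (T) roles are not fixed by any single convention; the shipped
#' defaults are the Rx-type N-terminal coiled-coil (IPR041118) and the
#' Toll/interleukin-1 receptor homology domain (IPR000157), both common in
#' legume NLR annotations. All sets are user-overridable.
#'
#' @return Named list of character vectors for roles N, L1, L2, L3, L4, C, T.
#' @export
default_role_map <- function() {
  list(
    N  = "IPR002182",
    L1 = "IPR001611",
    L2 = "IPR011713",
    L3 = "IPR013210",
    L4 = "IPR025875",
    C  = "IPR041118",
    T  = "IPR000157"
  )
}

#' Validate a domain-role map
#'
#' Role accession sets must be pairwise disjoint, the N and L1-L4 roles
#' non-empty, and every accession a well-formed InterPro identifier.
#'
#' @param roles Named list as returned by [default_role_map()].
#' @return The validated role map, invisibly usable downstream.
#' @export
validate_role_map <- function(roles) {
  required <- c("N", "L1", "L2", "L3", "L4", "C", "T")
  missing <- setdiff(required, names(roles))
  if (length(missing)) {
    stop("role map missing roles: ", paste(missing, collapse = ", "))
  }
  roles <- roles[required]
  roles <- lapply(roles, function(x) sort(unique(as.character(x))))
  for (r in c("N", "L1", "L2", "L3", "L4")) {
    if (!length(roles[[r]])) stop("role ", r, " must be non-empty")
  }
  all_acc <- unlist(roles, use.names = FALSE)
  bad <- all_acc[!grepl("^IPR[0-9]{6}$", all_acc)]
  if (length(bad)) {
    stop("malformed InterPro accession(s) in role map: ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(all_acc)) {
    stop("role accession sets must be pairwise disjoint; shared: ",
         paste(unique(all_acc[duplicated(all_acc)]), collapse = ", "))
  }
  roles
}

#' Read / write a role map as YAML
#'
#' @param path YAML file with one key per role.
#' @return [read_role_map()] returns a validated role map.
#' @export
read_role_map <- function(path) {
  validate_role_map(yaml::read_yaml(path))
}

#' @rdname read_role_map
#' @param roles Role map to serialize.
#' @export
write_role_map <- function(roles, path) {
  roles <- validate_role_map(roles)
  yaml::write_yaml(roles, path)
  invisible(path)
}

#' Stable hash of a role map
#'
#' Classification outputs record this hash so results are attributable to an
#' explicit role configuration.
#'
#' @param roles Role map.
#' @return Character md5 digest.
#' @export
role_map_hash <- function(roles) {
  roles <- validate_role_map(roles)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(roles), tmp)
  unname(tools::md5sum(tmp))
}

# Accessions tracked for candidate mining: N plus the four L roles.
tracked_accessions <- function(roles) {
  roles <- validate_role_map(roles)
  unlist(roles[c("N", "L1", "L2", "L3", "L4")], use.names = FALSE)
}
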