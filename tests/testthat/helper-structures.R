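# Builders for small synthetic structures used across tests.

# Build an spr_structure from a compact atom spec. `df` needs chain,
# resno, elety, x, y, z; other columns get sensible defaults.
make_structure <- function(df, id = "test") {
  n <- nrow(df)
  if (is.null(df$icode)) df$icode <- ""
  if (is.null(df$resid3)) df$resid3 <- "GLY"
  if (is.null(df$res_type)) {
    df$res_type <- unname(ppiprop:::AA3TO1[df$resid3])
    df$res_type[is.na(df$res_type)] <- "X"
  }
  if (is.null(df$element)) df$element <- substr(df$elety, 1, 1)
  if (is.null(df$occupancy)) df$occupancy <- 1
  if (is.null(df$vdw)) {
    df$vdw <- unname(ppiprop:::VDW_RADII[df$element])
    df$vdw[is.na(df$vdw)] <- ppiprop:::VDW_DEFAULT
  }
  df$is_sidechain <- !(df$elety %in% c("N", "CA", "C", "O", "OXT"))
  df$asa <- NA_real_
  df$res_id <- ppiprop:::res_id(df$chain, df$resno, df$icode)
  ppiprop:::new_structure(df, id = id)
}

# Structure from a build_backbone() data frame (single chain, one
# residue type).
backbone_structure <- function(bb, res_type = "A", chain = "A") {
  resid3 <- unname(ppiprop:::AA1TO3[res_type])
  make_structure(data.frame(
    chain = chain, resno = bb$resno, elety = bb$elety,
    resid3 = resid3, x = bb$x, y = bb$y, z = bb$z
  ))
}

# Minimal fake spr_interface carrying only a residue annotation table
# (enough for the propensity operations).
fake_annotation <- function(residues, cross_contacts = NULL,
                            interface_area = NULL, domain_asa = NULL,
                            id = "fake") {
  for (cl in c("icode", "ss")) if (is.null(residues[[cl]])) {
    residues[[cl]] <- NA_character_
  }
  iface <- split(residues$res_id[residues$class == "interface"],
                 residues$side[residues$class == "interface"])
  nonif <- split(residues$res_id[residues$class == "noninterface"],
                 residues$side[residues$class == "noninterface"])
  empty <- list(a = character(), b = character())
  iface <- utils::modifyList(empty, as.list(iface))
  nonif <- utils::modifyList(empty, as.list(nonif))
  if (is.null(cross_contacts)) {
    cross_contacts <- data.frame(a = character(), b = character())
  }
  if (is.null(interface_area)) {
    interface_area <- c(a = 0, b = 0)
  }
  if (is.null(domain_asa)) domain_asa <- c(a = 5000, b = 5000)
  structure(list(
    id = id, side_a = "A", side_b = "B",
    interface_residues = iface, noninterface_surface = nonif,
    delta_asa = stats::setNames(residues$delta_asa, residues$res_id),
    interface_area = interface_area, domain_asa = domain_asa,
    cross_contacts = cross_contacts, residues = residues
  ), class = "spr_interface")
}

# Residue annotation rows in the shape extract_interface() produces.
annotation_residues <- function(side, res_type, class, asa_unbound = 50,
                                delta_asa = NA_real_, ss = NA_character_) {
  n <- max(lengths(list(res_type, class, asa_unbound, delta_asa)))
  res_type <- rep_len(res_type, n)
  class <- rep_len(class, n)
  chain <- toupper(side)
  data.frame(
    side = side, res_id = paste0(chain, ":", seq_len(n), ":"),
    chain = chain, resno = seq_len(n), icode = "",
    res_type = res_type, asa_unbound = rep_len(asa_unbound, n),
    asa_bound = NA_real_, delta_asa = rep_len(delta_asa, n),
    ss = rep_len(ss, n), class = class, stringsAsFactors = FALSE
  )
}

# Training cases with the truth planted as the argmax patch at given
# weights; cases where the argmax is not separable from the weights in
# `discriminate_from` are dropped so the signal is identifiable.
planted_cases <- function(seeds, w_true, n_per_side = 40,
                          discriminate_from = NULL, n_target = Inf) {
  cases <- list()
  for (sd in seeds) {
    if (length(cases) >= n_target) break
    case <- toy_unbound_case(fixture_spec(seed = sd,
                                          n_per_side = n_per_side))
    prep <- ppiprop:::prepare_cases(list(case), use_cons = FALSE,
                                    use_sol = FALSE)[[1]]
    i_true <- ppiprop:::top_patch_index(prep, w_true)
    keep <- TRUE
    if (!is.null(discriminate_from)) {
      keep <- all(vapply(discriminate_from, function(w0)
        ppiprop:::top_patch_index(prep, w0) != i_true, logical(1)))
    }
    if (!keep) next
    cases[[length(cases) + 1]] <-
      list(struct = case$struct, truth = prep$patches[[i_true]]$members)
  }
  cases
}
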