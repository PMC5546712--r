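#' Default kinetic and abundance parameters of the CA1 signaling model
#'
#' All concentrations in nM, times in s, bimolecular rates in /nM/s.
#' Values are this package's parameterization of the pathway topology,
#' calibrated against the model's quantitative anchors: 30 nM basal cAMP,
#' ISO-driven pS845 fold increase of ~200% with no pS831 change, an
#' ultrasensitive beta2AR phosphorylation ladder, and the antagonist
#' Gi-recruitment ratios (carvedilol 1/3 of ISO; ERK proxy 10% propranolol /
#' 30% carvedilol).
#'
#' @return named list of parameters.
#' @export
ca1_params <- function() {
  list(
    # --- abundances (nM, within the species' region) ---
    ca_basal = 150, cab_tot = 20000, pmca_tot = 10000,
    cam_tot = 10000, ng_tot = 20000,
    ck_tot = 20000, pp2b_tot = 1000, pde1b_tot = 4000,
    ac1_tot = 1000, ac8_tot = 500, atp = 2e6,
    r_tot = 200, gs_tot = 3000, gi_tot = 2000,
    pka_tot = 1200, epac_tot = 800,
    i1_tot = 500, pp1_tot = 1000, pde4_tot = 1500,
    glur1_tot = 30000,
    # --- calcium handling ---
    cab_kf = 0.0075, cab_kr = 5.25,
    pmca_kf = 0.1, pmca_kr = 20, pmca_kcat = 25,
    # --- CaM / Ng ---
    cam_k12_kf = 0.004, cam_k12_kr = 2,      # C-lobe sites, Kd 500 nM
    cam_k34_kf = 0.025, cam_k34_kr = 87.5,   # N-lobe sites, Kd 3.5 uM
    ng_kf = 0.005, ng_kr = 5,
    # --- CaMKII ---
    ck_cam_kf = 5e-4, ck_cam_kr = 0.75,      # slow loading, Kd 1.5 uM
    ck_cplx_kf = 1e-4, ck_cplx_kr = 10, ck_auto = 0.5,
    pck_diss_kf = 0.1, pck_diss_kr = 0.01,
    pp1_ck_kf = 2e-4, pp1_ck_kr = 1, pp1_ck_kcat = 0.5,
    # --- PP2B, PDE1B ---
    pp2b_cam_kf = 0.02, pp2b_cam_kr = 0.1,
    pde1b_cam_kf = 0.03, pde1b_cam_kr = 1,
    pde1b_kf = 0.001, pde1b_kr = 8, pde1b_kcat = 10,
    # --- adenylyl cyclases ---
    ac1_cam_kf = 0.006, ac1_cam_kr = 2,
    ac1_gs_kf = 0.01, ac1_gs_kr = 3,
    ac_atp_kf = 1e-5, ac_atp_kr = 2.3,
    ac1_cam_kcat = 4, ac1_gs_kcat = 20, ac1_gscam_kcat = 250,
    ac1cam_gs_kf = 0.01, ac1cam_gs_kr = 0.3, ac1gs_cam_kf = 0.006, ac1gs_cam_kr = 0.09,
    ac1_basal_kf = 1e-7, ac1_basal_kr = 4.8, ac1_basal_kcat = 1.15,
    ac1_gi_kf = 0.01, ac1_gi_kr = 0.5,
    ac8_cam_kf = 0.002, ac8_cam_kr = 1.2, ac8_cam_kcat = 20,
    amp_regen = 10,
    # --- G proteins ---
    gs_hydrolysis = 2, gs_reassoc_kf = 0.006, gs_reassoc_kr = 0.001,
    gi_hydrolysis = 0.1, gi_reassoc_kf = 1e-3, gi_reassoc_kr = 0,
    # --- beta2AR ladder ---
    ne_kf = 0.005, ne_kr = 5,                # NE Kd 1 uM
    iso_kf = 0.01, iso_kr = 1,               # ISO Kd 100 nM
    rgs_kf = 3e-5, rgs_kr = 1, rgs_kcat = 2,
    pka_r_kf0 = 6e-5, pka_r_coop = 4,        # distributive, cooperative
    pka_r_kr = 4, pka_r_kcat = 2,
    r_dephos = 0.02,
    rgi_kf = 0.003, rgi_kr = 0.1, rgi_kcat = 0.5,
    prop_kf = 0.01, prop_kr = 0.03,
    ici_kf = 0.01, ici_kr = 0.01,
    carv_kf = 0.01, carv_kr = 0.01,
    prop_gi_kf = 4.4e-7, carv_gi_kf = 2.8e-6, # calibrated vs ISO Gi recruitment
    ant_gi_kr = 0.1, ant_gi_kcat = 0.5, carv_gi_kcat = 0.35,
    ne_clear = 4,
    # --- PKA (four cooperative cAMP sites, release from the 4-bound form) ---
    pka_camp_kf = 2e-3,
    pka_camp_kr = c(2, 1, 0.4, 0.2),         # Kd 1000, 500, 200, 100 nM
    pka_rel_kf = 5, pka_rel_kr = 0.1,
    # --- Epac ---
    epac_kf = 3e-5, epac_kr = 0.09,          # Kd 3 uM
    # --- I1 / PP1 ---
    i1_pka_kf = 2e-3, i1_pka_kr = 1, i1_pka_kcat = 2,
    ip35_pp1_kf = 0.01, ip35_pp1_kr = 0.01,
    ip35_pp2b_kf = 0.005, ip35_pp2b_kr = 1, ip35_pp2b_kcat = 5,
    # --- PDE4 ---
    pde4_kf = 0.0025, pde4_kr = 4, pde4_kcat = 3.5, ppde4_kcat = 14,
    pde4_pka_kf = 1.3e-3, pde4_pka_kr = 1, pde4_pka_kcat = 2,
    ppde4_dephos = 0.01,
    # --- GluA1 (kinases act through saturable PSD-anchored adaptor slots) ---
    a845_tot = 800, a845_kf = 0.02, a845_kr = 0.3,    # Km ~15 nM in PKAc
    a831_tot = 800, a831_kf = 0.02, a831_kr = 20,     # Km ~1 uM in CaMKII
    s845_kcat = 6e-6, s831_kcat = 1.1e-4, s831_bg = 1.4e-4,
    s831_bg_deph = 4e-3,
    glur1_pp1_s845_kf = 5e-5, glur1_pp1_s831_kf = 2e-5,
    glur1_pp1_kr = 1, glur1_pp1_kcat = 0.5,
    glur1_pp2b_kf = 3e-4, glur1_pp2b_kr = 1, glur1_pp2b_kcat = 1,
    # --- diffusion constants (um^2/s) ---
    D_ca = 100, D_camp = 300, D_atp = 140, D_cam = 10, D_ck = 0.1,
    D_lig = 300, D_small_prot = 5, D_epac = 2, D_pkac = 5, D_i1 = 10,
    D_cab = 10)
}

#' Build the CA1 dendrite/spine signaling model
#'
#' Constructs the full reaction network: calcium influx/extrusion and
#' buffering, calmodulin with neurogranin, CaMKII autophosphorylation via
#' paired-subunit complexes, calcineurin (PP2B), PDE1B, calcium/Gs-synergistic
#' adenylyl cyclases AC1 and AC8 with Gi inhibition, the beta2AR with a
#' cooperative, distributive four-site PKA phosphorylation ladder and Gs-Gi
#' coupling switch, Gs/Gi nucleotide cycles, PKA holoenzyme activation by
#' cAMP, Epac, Inhibitor-1/PP1, PDE4 with PKA-mediated feedback
#' phosphorylation, antagonist binding (propranolol, ICI-118,551,
#' carvedilol) with Gi recruitment by the propranolol- and carvedilol-bound
#' receptor, and GluA1 phosphorylation at S845/S831.
#'
#' @param params parameter list from [ca1_params()]; individual entries can
#'   be overridden.
#' @return a `sig_model` with declared conserved moieties and signature
#'   component sets attached (`m$signatures`).
#' @export
ca1_model <- function(params = ca1_params()) {
  p <- utils::modifyList(ca1_params(), params)
  SP <- list(); RX <- list(); COMP <- list()
  sp <- function(name, loc = "cyt", D = 0, init = 0, comp = c()) {
    SP[[name]] <<- sig_species(name, loc, D, init)
    COMP[[name]] <<- comp
    name
  }
  rx <- function(eq, kf, kr = 0, tag = "") {
    RX[[length(RX) + 1L]] <<- sig_reaction(eq, kf, kr, tag)
    invisible(NULL)
  }
  merge_comp <- function(a, b) {
    for (nm in names(b)) a[nm] <- (if (nm %in% names(a)) a[[nm]] else 0) + b[[nm]]
    a
  }

  ## calcium handling ------------------------------------------------------
  sp("Ca", "cyt", p$D_ca, p$ca_basal)
  sp("CaB", "cyt", p$D_cab, p$cab_tot, c(CaB = 1))
  sp("CaBCa", "cyt", p$D_cab, 0, c(CaB = 1))
  sp("pmca", "sub", 0, p$pmca_tot, c(pmca = 1))
  sp("pmcaCa", "sub", 0, 0, c(pmca = 1))
  sp("CaLeak", "sub", 0, 1000)
  rx("Ca + CaB <-> CaBCa", p$cab_kf, p$cab_kr, "calcium")
  rx("Ca + pmca <-> pmcaCa", p$pmca_kf, p$pmca_kr, "calcium")
  rx("pmcaCa -> pmca", p$pmca_kcat, tag = "calcium")
  # membrane leak balancing the pump at basal calcium
  frac <- p$ca_basal * p$pmca_kf / (p$pmca_kr + p$pmca_kcat)
  pmca_ca_ss <- p$pmca_tot * frac / (1 + frac)
  # CaB equilibrium at basal
  cab_bound <- p$cab_tot * p$ca_basal * p$cab_kf /
    (p$cab_kr + p$ca_basal * p$cab_kf)
  SP[["CaB"]]$init <- p$cab_tot - cab_bound
  SP[["CaBCa"]]$init <- cab_bound
  SP[["pmca"]]$init <- p$pmca_tot - pmca_ca_ss
  SP[["pmcaCa"]]$init <- pmca_ca_ss
  rx("CaLeak -> CaLeak + Ca", p$pmca_kcat * pmca_ca_ss / 1000,
     tag = "calcium")

  ## calmodulin / neurogranin ----------------------------------------------
  sp("CaM", "cyt", p$D_cam, NA, c(CaM = 1))
  for (s in c("CaMCa", "CaMCa2", "CaMCa3", "CaMCa4"))
    sp(s, "cyt", p$D_cam, 0, c(CaM = 1))
  sp("Ng", "cyt", p$D_cam, NA, c(Ng = 1))
  sp("NgCaM", "cyt", p$D_cam, 0, c(Ng = 1, CaM = 1))
  rx("CaM + Ca <-> CaMCa", p$cam_k12_kf, p$cam_k12_kr, "CaM")
  rx("CaMCa + Ca <-> CaMCa2", p$cam_k12_kf, p$cam_k12_kr, "CaM")
  rx("CaMCa2 + Ca <-> CaMCa3", p$cam_k34_kf, p$cam_k34_kr, "CaM")
  rx("CaMCa3 + Ca <-> CaMCa4", p$cam_k34_kf, p$cam_k34_kr, "CaM")
  rx("CaM + Ng <-> NgCaM", p$ng_kf, p$ng_kr, "CaM")
  # approximate basal partition of CaM between Ng and low Ca occupancy
  ng_bound <- p$cam_tot * 0.6
  SP[["CaM"]]$init <- p$cam_tot - ng_bound
  SP[["NgCaM"]]$init <- ng_bound
  SP[["Ng"]]$init <- p$ng_tot - ng_bound

  ## CaMKII -----------------------------------------------------------------
  sp("CaMKII", "cyt", p$D_ck, p$ck_tot, c(CaMKII = 1))
  sp("CKCaM", "cyt", p$D_ck, 0, c(CaMKII = 1, CaM = 1))
  sp("CKComplex", "cyt", p$D_ck, 0, c(CaMKII = 2, CaM = 2))
  sp("pCKComplex", "cyt", p$D_ck, 0, c(CaMKII = 2, CaM = 2))
  sp("pCKCaM", "cyt", p$D_ck, 0, c(CaMKII = 1, CaM = 1))
  sp("pCaMKII", "cyt", p$D_ck, 0, c(CaMKII = 1))
  sp("pCaMKIIPP1", "cyt", 0, 0, c(CaMKII = 1, PP1 = 1))
  sp("pCKCaMPP1", "cyt", 0, 0, c(CaMKII = 1, CaM = 1, PP1 = 1))
  rx("CaMKII + CaMCa4 <-> CKCaM", p$ck_cam_kf, p$ck_cam_kr, "CaMKII")
  rx("2 CKCaM <-> CKComplex", p$ck_cplx_kf, p$ck_cplx_kr, "CaMKII")
  rx("CKComplex -> pCKCaM + CKCaM", p$ck_auto, tag = "CaMKII")
  rx("pCKCaM + CKCaM <-> pCKComplex", p$ck_cplx_kf, p$ck_cplx_kr, "CaMKII")
  rx("pCKComplex -> 2 pCKCaM", p$ck_auto, tag = "CaMKII")
  rx("pCKCaM <-> pCaMKII + CaMCa4", p$pck_diss_kf, p$pck_diss_kr, "CaMKII")
  rx("pCaMKII + PP1 <-> pCaMKIIPP1", p$pp1_ck_kf, p$pp1_ck_kr, "CaMKII")
  rx("pCaMKIIPP1 -> CaMKII + PP1", p$pp1_ck_kcat, tag = "CaMKII")
  rx("pCKCaM + PP1 <-> pCKCaMPP1", p$pp1_ck_kf, p$pp1_ck_kr, "CaMKII")
  rx("pCKCaMPP1 -> CKCaM + PP1", p$pp1_ck_kcat, tag = "CaMKII")

  ## PP2B (calcineurin) and PDE1B -------------------------------------------
  sp("PP2B", "cyt", p$D_small_prot, p$pp2b_tot, c(PP2B = 1))
  sp("PP2BCaM", "cyt", p$D_small_prot, 0, c(PP2B = 1, CaM = 1))
  rx("PP2B + CaMCa4 <-> PP2BCaM", p$pp2b_cam_kf, p$pp2b_cam_kr, "PP2B")
  sp("PDE1B", "cyt", p$D_small_prot, p$pde1b_tot, c(PDE1B = 1))
  sp("PDE1BCaM", "cyt", p$D_small_prot, 0, c(PDE1B = 1, CaM = 1))
  sp("PDE1BCaMcAMP", "cyt", 0, 0, c(PDE1B = 1, CaM = 1, Ade = 1))
  rx("PDE1B + CaMCa4 <-> PDE1BCaM", p$pde1b_cam_kf, p$pde1b_cam_kr, "PDE1B")
  rx("PDE1BCaM + cAMP <-> PDE1BCaMcAMP", p$pde1b_kf, p$pde1b_kr, "PDE1B")
  rx("PDE1BCaMcAMP -> PDE1BCaM + AMP", p$pde1b_kcat, tag = "PDE1B")

  ## nucleotides -------------------------------------------------------------
  sp("ATP", "cyt", p$D_atp, p$atp, c(Ade = 1))
  sp("cAMP", "cyt", p$D_camp, 30, c(Ade = 1))
  sp("AMP", "cyt", p$D_atp, 0, c(Ade = 1))
  rx("AMP -> ATP", p$amp_regen, tag = "nucleotide")

  ## adenylyl cyclases --------------------------------------------------------
  ac_states <- function(base, tot) {
    sp(base, "sub", 0, tot, structure(1, names = base))
  }
  ac_states("AC1", p$ac1_tot)
  for (s in c("AC1CaM", "AC1CaMATP", "AC1Gs", "AC1GsATP", "AC1GsCaM",
              "AC1GsCaMATP", "AC1GsGiCaM", "AC1GsGi", "AC1GiCaM", "AC1Gi",
              "AC1bATP"))
    sp(s, "sub", 0, 0, c(AC1 = 1,
                         if (grepl("ATP", s)) c(Ade = 1),
                         if (grepl("Gs", s)) c(Gsa = 1),
                         if (grepl("Gi", s)) c(Gia = 1),
                         if (grepl("CaM", s)) c(CaM = 1)))
  rx("AC1 + CaMCa4 <-> AC1CaM", p$ac1_cam_kf, p$ac1_cam_kr, "AC")
  rx("AC1CaM + ATP <-> AC1CaMATP", p$ac_atp_kf, p$ac_atp_kr, "AC")
  rx("AC1CaMATP -> AC1CaM + cAMP", p$ac1_cam_kcat, tag = "AC")
  rx("AC1 + GsaGTP <-> AC1Gs", p$ac1_gs_kf, p$ac1_gs_kr, "AC")
  rx("AC1Gs + ATP <-> AC1GsATP", p$ac_atp_kf, p$ac_atp_kr, "AC")
  rx("AC1GsATP -> AC1Gs + cAMP", p$ac1_gs_kcat, tag = "AC")
  rx("AC1Gs + CaMCa4 <-> AC1GsCaM", p$ac1gs_cam_kf, p$ac1gs_cam_kr, "AC")
  rx("AC1CaM + GsaGTP <-> AC1GsCaM", p$ac1cam_gs_kf, p$ac1cam_gs_kr, "AC")
  rx("AC1GsCaM + ATP <-> AC1GsCaMATP", p$ac_atp_kf, p$ac_atp_kr, "AC")
  rx("AC1GsCaMATP -> AC1GsCaM + cAMP", p$ac1_gscam_kcat, tag = "AC")
  rx("AC1 + ATP <-> AC1bATP", p$ac1_basal_kf, p$ac1_basal_kr, "AC")
  rx("AC1bATP -> AC1 + cAMP", p$ac1_basal_kcat, tag = "AC")
  # Gi inhibition: Gi-bound cyclase states are catalytically silent
  rx("AC1GsCaM + GiaGTP <-> AC1GsGiCaM", p$ac1_gi_kf, p$ac1_gi_kr, "AC")
  rx("AC1Gs + GiaGTP <-> AC1GsGi", p$ac1_gi_kf, p$ac1_gi_kr, "AC")
  rx("AC1CaM + GiaGTP <-> AC1GiCaM", p$ac1_gi_kf / 2, p$ac1_gi_kr, "AC")
  rx("AC1 + GiaGTP <-> AC1Gi", p$ac1_gi_kf / 2, p$ac1_gi_kr, "AC")
  ac_states("AC8", p$ac8_tot)
  sp("AC8CaM", "sub", 0, 0, c(AC8 = 1, CaM = 1))
  sp("AC8CaMATP", "sub", 0, 0, c(AC8 = 1, CaM = 1, Ade = 1))
  sp("AC8bATP", "sub", 0, 0, c(AC8 = 1, Ade = 1))
  rx("AC8 + CaMCa4 <-> AC8CaM", p$ac8_cam_kf, p$ac8_cam_kr, "AC")
  rx("AC8CaM + ATP <-> AC8CaMATP", p$ac_atp_kf, p$ac_atp_kr, "AC")
  rx("AC8CaMATP -> AC8CaM + cAMP", p$ac8_cam_kcat, tag = "AC")
  rx("AC8 + ATP <-> AC8bATP", p$ac1_basal_kf, p$ac1_basal_kr, "AC")
  rx("AC8bATP -> AC8 + cAMP", p$ac1_basal_kcat, tag = "AC")

  ## G protein cycles ---------------------------------------------------------
  sp("Gs", "sub", 0, p$gs_tot, c(Gsa = 1, Gsbg = 1))
  sp("GsaGTP", "sub", 0, 0, c(Gsa = 1))
  sp("GsaGDP", "sub", 0, 0, c(Gsa = 1))
  sp("Gsbg", "sub", 0, 0, c(Gsbg = 1))
  sp("Gi", "sub", 0, p$gi_tot, c(Gia = 1, Gibg = 1))
  sp("GiaGTP", "sub", 0, 0, c(Gia = 1))
  sp("GiaGDP", "sub", 0, 0, c(Gia = 1))
  sp("Gibg", "sub", 0, 0, c(Gibg = 1))
  rx("GsaGTP -> GsaGDP", p$gs_hydrolysis, tag = "Gprotein")
  rx("GsaGDP + Gsbg <-> Gs", p$gs_reassoc_kf, p$gs_reassoc_kr, "Gprotein")
  rx("GiaGTP -> GiaGDP", p$gi_hydrolysis, tag = "Gprotein")
  rx("GiaGDP + Gibg -> Gi", p$gi_reassoc_kf, tag = "Gprotein")

  ## beta2AR ladder ------------------------------------------------------------
  sp("NE", "cyt", p$D_lig, 0)
  sp("ISO", "cyt", p$D_lig, 0)
  sp("Prop", "cyt", p$D_lig, 0)
  sp("ICI", "cyt", p$D_lig, 0)
  sp("Carv", "cyt", p$D_lig, 0)
  rx("NE -> ", p$ne_clear, tag = "ligand")
  pre <- c("", "p", "pp", "ppp", "pppp")
  ladder <- function(stem, lig = NULL, lig_kf = 0, lig_kr = 0) {
    # receptor phospho states stem, p<stem>, ..., pppp<stem>
    for (i in 0:4)
      sp(paste0(pre[i + 1], stem), "sub", 0, 0, c(B2AR = 1))
    for (i in 0:3) {
      x <- paste0(pre[i + 1], stem)
      xp <- paste0(pre[i + 2], stem)
      cplx <- paste0("PKAc", x)
      sp(cplx, "sub", 0, 0, c(B2AR = 1, PKAC = 1))
      kf_i <- p$pka_r_kf0 * p$pka_r_coop^i
      rx(paste0(x, " + PKAc <-> ", cplx), kf_i, p$pka_r_kr, "PKAc")
      rx(paste0(cplx, " -> ", xp, " + PKAc"), p$pka_r_kcat, tag = "PKAc")
      rx(paste0(xp, " -> ", x), p$r_dephos, tag = "B2AR")
    }
    if (!is.null(lig))
      rx(paste0("R + ", lig, " <-> ", stem), lig_kf, lig_kr, "B2AR")
    # Gi binding only at full phosphorylation
    gi_c <- paste0("pppp", stem, "Gi")
    sp(gi_c, "sub", 0, 0, c(B2AR = 1, Gia = 1, Gibg = 1))
    rx(paste0("pppp", stem, " + Gi <-> ", gi_c), p$rgi_kf, p$rgi_kr, "B2AR")
    rx(paste0(gi_c, " -> pppp", stem, " + GiaGTP + Gibg"), p$rgi_kcat,
       tag = "B2AR")
    gi_c
  }
  ladder("R")
  ladder("NER", "NE", p$ne_kf, p$ne_kr)
  ladder("ISOR", "ISO", p$iso_kf, p$iso_kr)
  # Gs activation by agonist-bound unphosphorylated receptor only
  for (ag in c("NER", "ISOR")) {
    cplx <- paste0(ag, "Gs")
    sp(cplx, "sub", 0, 0, c(B2AR = 1, Gsa = 1, Gsbg = 1))
    rx(paste0(ag, " + Gs <-> ", cplx), p$rgs_kf, p$rgs_kr, "B2AR")
    rx(paste0(cplx, " -> ", ag, " + GsaGTP + Gsbg"), p$rgs_kcat, tag = "B2AR")
  }
  # antagonists; propranolol- and carvedilol-bound receptor recruit Gi
  for (ant in c("Prop", "ICI", "Carv")) {
    b <- paste0(ant, "R")
    sp(b, "sub", 0, 0, c(B2AR = 1))
    kfkr <- switch(ant, Prop = c(p$prop_kf, p$prop_kr),
                   ICI = c(p$ici_kf, p$ici_kr),
                   Carv = c(p$carv_kf, p$carv_kr))
    rx(paste0("R + ", ant, " <-> ", b), kfkr[1], kfkr[2], "antagonist")
    if (ant != "ICI") {
      gi_c <- paste0(b, "Gi")
      sp(gi_c, "sub", 0, 0, c(B2AR = 1, Gia = 1, Gibg = 1))
      gkf <- if (ant == "Prop") p$prop_gi_kf else p$carv_gi_kf
      gkc <- if (ant == "Prop") p$ant_gi_kcat else p$carv_gi_kcat
      rx(paste0(b, " + Gi <-> ", gi_c), gkf, p$ant_gi_kr, "antagonist")
      rx(paste0(gi_c, " -> ", b, " + GiaGTP + Gibg"), gkc,
         tag = "antagonist")
    }
  }
  SP[["R"]]$init <- p$r_tot

  ## PKA ------------------------------------------------------------------------
  sp("PKA", "sub", 0, p$pka_tot, c(PKAR = 1, PKAC = 2))
  for (i in 1:4)
    sp(paste0("PKAcAMP", i), "sub", 0, 0, c(PKAR = 1, PKAC = 2, Ade = i))
  sp("PKArC", "sub", 0, 0, c(PKAR = 1, PKAC = 1, Ade = 4))
  sp("PKAr", "sub", 0, 0, c(PKAR = 1, Ade = 4))
  sp("PKAc", "cyt", p$D_pkac, 0, c(PKAC = 1))
  rx("PKA + cAMP <-> PKAcAMP1", p$pka_camp_kf, p$pka_camp_kr[1], "PKA")
  for (i in 2:4)
    rx(paste0("PKAcAMP", i - 1, " + cAMP <-> PKAcAMP", i),
       p$pka_camp_kf, p$pka_camp_kr[i], "PKA")
  rx("PKAcAMP4 <-> PKArC + PKAc", p$pka_rel_kf, p$pka_rel_kr, "PKA")
  rx("PKArC <-> PKAr + PKAc", p$pka_rel_kf, p$pka_rel_kr, "PKA")

  ## Epac -------------------------------------------------------------------------
  sp("Epac", "cyt", p$D_epac, p$epac_tot, c(Epac = 1))
  sp("EpaccAMP", "cyt", p$D_epac, 0, c(Epac = 1, Ade = 1))
  rx("Epac + cAMP <-> EpaccAMP", p$epac_kf, p$epac_kr, "Epac")

  ## Inhibitor-1 / PP1 ---------------------------------------------------------------
  sp("I1", "cyt", p$D_i1, p$i1_tot, c(I1 = 1))
  sp("I1PKAc", "cyt", 0, 0, c(I1 = 1, PKAC = 1))
  sp("Ip35", "cyt", p$D_i1, 0, c(I1 = 1))
  sp("PP1", "cyt", p$D_small_prot, p$pp1_tot, c(PP1 = 1))
  sp("Ip35PP1", "cyt", 0, 0, c(I1 = 1, PP1 = 1))
  sp("Ip35PP2B", "cyt", 0, 0, c(I1 = 1, PP2B = 1, CaM = 1))
  rx("I1 + PKAc <-> I1PKAc", p$i1_pka_kf, p$i1_pka_kr, "PKAc")
  rx("I1PKAc -> Ip35 + PKAc", p$i1_pka_kcat, tag = "PKAc")
  rx("Ip35 + PP1 <-> Ip35PP1", p$ip35_pp1_kf, p$ip35_pp1_kr, "I1PP1")
  rx("Ip35 + PP2BCaM <-> Ip35PP2B", p$ip35_pp2b_kf, p$ip35_pp2b_kr, "I1PP1")
  rx("Ip35PP2B -> I1 + PP2BCaM", p$ip35_pp2b_kcat, tag = "I1PP1")

  ## PDE4 ------------------------------------------------------------------------------
  sp("PDE4", "sub", 0, p$pde4_tot, c(PDE4 = 1))
  sp("PDE4cAMP", "sub", 0, 0, c(PDE4 = 1, Ade = 1))
  sp("PDE4PKAc", "sub", 0, 0, c(PDE4 = 1, PKAC = 1))
  sp("pPDE4", "sub", 0, 0, c(PDE4 = 1))
  sp("pPDE4cAMP", "sub", 0, 0, c(PDE4 = 1, Ade = 1))
  rx("PDE4 + cAMP <-> PDE4cAMP", p$pde4_kf, p$pde4_kr, "PDE4")
  rx("PDE4cAMP -> PDE4 + AMP", p$pde4_kcat, tag = "PDE4")
  rx("PDE4 + PKAc <-> PDE4PKAc", p$pde4_pka_kf, p$pde4_pka_kr, "PKAc")
  rx("PDE4PKAc -> pPDE4 + PKAc", p$pde4_pka_kcat, tag = "PKAc")
  rx("pPDE4 + cAMP <-> pPDE4cAMP", p$pde4_kf, p$pde4_kr, "PDE4")
  rx("pPDE4cAMP -> pPDE4 + AMP", p$ppde4_kcat, tag = "PDE4")
  rx("pPDE4 -> PDE4", p$ppde4_dephos, tag = "PDE4")

  ## GluA1 -----------------------------------------------------------------
  # Kinases act on GluA1 through a limited pool of PSD-anchored adaptor
  # slots (AKAP-anchored PKA, NMDAR-bound CaMKII), which makes S845/S831
  # phosphorylation saturable in kinase activity.
  sp("GluR1", "psd", 0, p$glur1_tot, c(GluR1 = 1))
  for (s in c("pS845", "pS831", "pS845pS831"))
    sp(s, "psd", 0, 0, c(GluR1 = 1))
  sp("A845", "psd", 0, p$a845_tot, c(A845 = 1))
  sp("A845PKAc", "psd", 0, 0, c(A845 = 1, PKAC = 1))
  sp("A831", "psd", 0, p$a831_tot, c(A831 = 1))
  sp("A831pCK", "psd", 0, 0, c(A831 = 1, CaMKII = 1, CaM = 1))
  sp("A831pCKa", "psd", 0, 0, c(A831 = 1, CaMKII = 1))
  rx("A845 + PKAc <-> A845PKAc", p$a845_kf, p$a845_kr, "PKAc")
  # S831 is phosphorylated by autonomous (T286-phosphorylated) CaMKII
  rx("A831 + pCKCaM <-> A831pCK", p$a831_kf, p$a831_kr, "GluR1")
  rx("A831 + pCaMKII <-> A831pCKa", p$a831_kf, p$a831_kr, "GluR1")
  rx("A845PKAc + GluR1 -> A845PKAc + pS845", p$s845_kcat, tag = "PKAc")
  rx("A845PKAc + pS831 -> A845PKAc + pS845pS831", p$s845_kcat, tag = "PKAc")
  rx("A831pCK + GluR1 -> A831pCK + pS831", p$s831_kcat, tag = "GluR1")
  rx("A831pCKa + GluR1 -> A831pCKa + pS831", p$s831_kcat, tag = "GluR1")
  rx("A831pCK + pS845 -> A831pCK + pS845pS831", p$s831_kcat, tag = "GluR1")
  rx("A831pCKa + pS845 -> A831pCKa + pS845pS831", p$s831_kcat, tag = "GluR1")
  # constitutive background S831 phosphorylation and dephosphorylation
  # (basal PKC-class activity; PP1-independent phosphatase component)
  rx("GluR1 -> pS831", p$s831_bg, tag = "GluR1")
  rx("pS845 -> pS845pS831", p$s831_bg, tag = "GluR1")
  rx("pS831 -> GluR1", p$s831_bg_deph, tag = "GluR1")
  rx("pS845pS831 -> pS845", p$s831_bg_deph, tag = "GluR1")
  # dephosphorylation by PP1 (both sites) and PP2B (S845)
  phos <- function(sub, prod, phase, kf, tag = "GluR1") {
    cplx <- paste0(sub, "_", phase)
    sp(cplx, "psd", 0, 0, merge_comp(c(GluR1 = 1), COMP[[phase]]))
    rx(paste0(sub, " + ", phase, " <-> ", cplx), kf, p$glur1_pp1_kr, tag)
    rx(paste0(cplx, " -> ", prod, " + ", phase),
       if (phase == "PP2BCaM") p$glur1_pp2b_kcat else p$glur1_pp1_kcat,
       tag = tag)
  }
  phos("pS845", "GluR1", "PP1", p$glur1_pp1_s845_kf)
  phos("pS845", "GluR1", "PP2BCaM", p$glur1_pp2b_kf)
  phos("pS831", "GluR1", "PP1", p$glur1_pp1_s831_kf)
  phos("pS845pS831", "pS845", "PP1", p$glur1_pp1_s831_kf)
  phos("pS845pS831", "pS831", "PP2BCaM", p$glur1_pp2b_kf)

  ## assemble -----------------------------------------------------------------------
  species <- do.call(rbind, SP)
  moieties <- list()
  for (mo in unique(unlist(lapply(COMP, names)))) {
    w <- vapply(COMP, function(cc) if (mo %in% names(cc)) cc[[mo]] else 0,
                0)
    names(w) <- names(COMP)
    moieties[[mo]] <- w[w != 0]
  }
  # adenine is open through bath-free AC/PDE only; it is closed in this
  # network (AMP -> ATP regeneration) and worth asserting
  m <- sig_model(species, RX, name = "ca1-signaling", moieties = moieties)
  m$params <- p
  m$signatures <- list(
    spine = list(
      pCaMKII = c("pCKCaM", "pCaMKII", "pCKComplex", "pCaMKIIPP1",
                  "pCKCaMPP1"),
      Epac = "EpaccAMP",
      PKA = c("pPDE4", "pPDE4cAMP", "Ip35", "Ip35PP1", "Ip35PP2B",
              "pS845", "pS845pS831",
              grep("^p+R$|^p+NER$|^p+ISOR$", names(SP), value = TRUE))),
    dendrite = list(
      Epac = "EpaccAMP",
      pCaMKII = c("pCKCaM", "pCaMKII", "pCKComplex", "pCaMKIIPP1",
                  "pCKCaMPP1"),
      pI1pPDE4 = c("Ip35", "Ip35PP1", "Ip35PP2B", "pPDE4", "pPDE4cAMP"),
      Gi = "Gibg"),
    erk_proxy = c("Gibg"),
    gi_bound_receptor = grep("Gi$", names(SP), value = TRUE))
  m$signatures$gi_bound_receptor <-
    setdiff(m$signatures$gi_bound_receptor, c("Gi", "AC1GsGi", "AC1Gi"))
  m
}
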