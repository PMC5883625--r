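# Packaged reduced central-carbon model of Aureobasidium pullulans.
#
# A compact, fully auditable stand-in for a genome-scale reconstruction:
# lumped glycolysis, sucrose and fructose entry, the pyruvate node, a full
# oxidative TCA cycle with each enzyme as its own reaction, the reductive
# cytosolic branch (pyruvate carboxylase + cytosolic malate dehydrogenase),
# the glyoxylate shunt with its cytosolic support reactions, oxidative
# phosphorylation at documented P/O ratios, ATP maintenance, PMA synthesis
# from cytosolic malate, and a lumped biomass pseudo-reaction. Three
# compartments (cytosol, mitochondrion, extracellular) with explicit
# transporters. Every internal reaction is carbon-balanced; hydrogen and
# oxygen are tracked only up to free water, protons and inorganic
# phosphate, which are marked as bookkeeping species.

#' Build the packaged reduced A. pullulans central-carbon model
#'
#' Returns the model used throughout the package for route scanning. Key
#' conventions, all recorded in the model notes:
#' \itemize{
#'   \item Glucose uptake bounded at 10 mmol/gDW/h; sucrose entry is
#'     carbon- and energy-neutral (invertase hydrolysis, no ATP cost) and
#'     disabled by default (enabled by the scan functions at the
#'     hexose-equivalent rate of 5 mmol/gDW/h).
#'   \item Lumped glycolysis: hexose -> 2 pyruvate + 2 ATP + 2 NADH.
#'   \item P/O ratios 1.5 (NADH) and 1.0 (FADH2); an ATP maintenance
#'     reaction (default lower bound 0, so it constrains only when a user
#'     imposes it); respiratory O2 uptake capped at 20 mmol/gDW/h.
#'   \item PMA synthesis polymerises cytosolic malate at a cost of 1 ATP
#'     per residue, releasing one water per ester bond.
#'   \item Mitochondrial and cytosolic malate dehydrogenase are distinct
#'     reactions (`MDH_m`, `MDH_c`); the route scan fixes `MDH_m` to 0.
#'   \item Biomass drains pyruvate (6 per unit flux) plus 20 ATP; the
#'     biomass flux axis is labelled gDW/h.
#' }
#'
#' @return A validated `"metabolic_model"` with objective `PMAS`
#'   (PMA synthesis).
#' @export
#' @examples
#' m <- build_reduced_model()
#' subset(carbon_balance_report(m), !exempt & carbon_imbalance != 0)
build_reduced_model <- function() {
  met <- function(id, name, comp, C, H, O, N = 0, P = 0, S = 0, book = FALSE)
    metabolite(id, name, comp,
               formula = c(C = C, H = H, O = O, N = N, P = P, S = S),
               bookkeeping = book)
  mets <- list(
    met("glc_e", "D-glucose", "extracellular", 6, 12, 6),
    met("glc_c", "D-glucose", "cytosol", 6, 12, 6),
    met("fru_c", "D-fructose", "cytosol", 6, 12, 6),
    met("suc_e", "sucrose", "extracellular", 12, 22, 11),
    met("suc_c", "sucrose", "cytosol", 12, 22, 11),
    met("pyr_c", "pyruvate", "cytosol", 3, 4, 3),
    met("pyr_m", "pyruvate", "mitochondrion", 3, 4, 3),
    met("pyr_e", "pyruvate", "extracellular", 3, 4, 3),
    met("oaa_c", "oxaloacetate", "cytosol", 4, 4, 5),
    met("oaa_m", "oxaloacetate", "mitochondrion", 4, 4, 5),
    met("mal_c", "L-malate", "cytosol", 4, 6, 5),
    met("mal_m", "L-malate", "mitochondrion", 4, 6, 5),
    met("fum_c", "fumarate", "cytosol", 4, 4, 4),
    met("fum_m", "fumarate", "mitochondrion", 4, 4, 4),
    met("succ_c", "succinate", "cytosol", 4, 6, 4),
    met("succ_m", "succinate", "mitochondrion", 4, 6, 4),
    met("succ_e", "succinate", "extracellular", 4, 6, 4),
    met("cit_c", "citrate", "cytosol", 6, 8, 7),
    met("cit_m", "citrate", "mitochondrion", 6, 8, 7),
    met("icit_c", "isocitrate", "cytosol", 6, 8, 7),
    met("icit_m", "isocitrate", "mitochondrion", 6, 8, 7),
    met("akg_m", "2-oxoglutarate", "mitochondrion", 5, 6, 5),
    met("glx_c", "glyoxylate", "cytosol", 2, 2, 3),
    met("accoa_c", "acetyl-CoA", "cytosol", 23, 38, 17, N = 7, P = 3, S = 1),
    met("accoa_m", "acetyl-CoA", "mitochondrion", 23, 38, 17, N = 7, P = 3, S = 1),
    met("coa_c", "coenzyme A", "cytosol", 21, 36, 16, N = 7, P = 3, S = 1),
    met("coa_m", "coenzyme A", "mitochondrion", 21, 36, 16, N = 7, P = 3, S = 1),
    met("succoa_m", "succinyl-CoA", "mitochondrion", 25, 40, 19, N = 7, P = 3, S = 1),
    met("atp_c", "ATP", "cytosol", 10, 16, 13, N = 5, P = 3),
    met("atp_m", "ATP", "mitochondrion", 10, 16, 13, N = 5, P = 3),
    met("adp_c", "ADP", "cytosol", 10, 15, 10, N = 5, P = 2),
    met("adp_m", "ADP", "mitochondrion", 10, 15, 10, N = 5, P = 2),
    met("pi_c", "phosphate", "cytosol", 0, 3, 4, P = 1, book = TRUE),
    met("pi_m", "phosphate", "mitochondrion", 0, 3, 4, P = 1, book = TRUE),
    met("nad_c", "NAD+", "cytosol", 21, 27, 14, N = 7, P = 2),
    met("nad_m", "NAD+", "mitochondrion", 21, 27, 14, N = 7, P = 2),
    met("nadh_c", "NADH", "cytosol", 21, 28, 14, N = 7, P = 2),
    met("nadh_m", "NADH", "mitochondrion", 21, 28, 14, N = 7, P = 2),
    met("fad_m", "FAD", "mitochondrion", 27, 33, 15, N = 9, P = 2),
    met("fadh2_m", "FADH2", "mitochondrion", 27, 35, 15, N = 9, P = 2),
    met("o2_e", "oxygen", "extracellular", 0, 0, 2),
    met("o2_c", "oxygen", "cytosol", 0, 0, 2),
    met("co2_e", "carbon dioxide", "extracellular", 1, 0, 2),
    met("co2_c", "carbon dioxide", "cytosol", 1, 0, 2),
    met("co2_m", "carbon dioxide", "mitochondrion", 1, 0, 2),
    met("h2o_e", "water", "extracellular", 0, 2, 1, book = TRUE),
    met("h2o_c", "water", "cytosol", 0, 2, 1, book = TRUE),
    met("h2o_m", "water", "mitochondrion", 0, 2, 1, book = TRUE),
    met("pma_c", "polymalate residue", "cytosol", 4, 4, 4),
    met("pma_e", "polymalate residue", "extracellular", 4, 4, 4),
    met("biomass_e", "biomass", "extracellular", 18, 30, 15))

  rx <- function(id, st, name = id, lb = 0, ub = 1000, kind = "internal")
    reaction(id, st, name = name, lower_bound = lb, upper_bound = ub,
             kind = kind)
  rxns <- list(
    # exchanges (negative flux = uptake)
    rx("EX_glc", c(glc_e = -1), "glucose exchange", lb = -10, ub = 0,
       kind = "exchange"),
    rx("EX_suc", c(suc_e = -1), "sucrose exchange", lb = 0, ub = 0,
       kind = "exchange"),
    rx("EX_o2", c(o2_e = -1), "oxygen exchange", lb = -20, ub = 0,
       kind = "exchange"),
    rx("EX_co2", c(co2_e = -1), "CO2 exchange", lb = -1000, ub = 1000,
       kind = "exchange"),
    rx("EX_h2o", c(h2o_e = -1), "water exchange", lb = -1000, ub = 1000,
       kind = "exchange"),
    rx("EX_pma", c(pma_e = -1), "PMA exchange", kind = "exchange"),
    rx("EX_pyr", c(pyr_e = -1), "pyruvate exchange", kind = "exchange"),
    rx("EX_succ", c(succ_e = -1), "succinate exchange", kind = "exchange"),
    rx("EX_biomass", c(biomass_e = -1), "biomass exchange",
       kind = "exchange"),
    # transport
    rx("GLCt", c(glc_e = -1, glc_c = 1), "glucose transport"),
    rx("SUCt", c(suc_e = -1, suc_c = 1), "sucrose transport"),
    rx("O2t", c(o2_e = -1, o2_c = 1), "oxygen transport"),
    rx("CO2t", c(co2_e = -1, co2_c = 1), "CO2 transport", lb = -1000),
    rx("CO2tm", c(co2_c = -1, co2_m = 1), "CO2 transport, mitochondrial",
       lb = -1000),
    rx("H2Ot", c(h2o_e = -1, h2o_c = 1), "water transport", lb = -1000),
    rx("H2Otm", c(h2o_c = -1, h2o_m = 1), "water transport, mitochondrial",
       lb = -1000),
    rx("PYRt_m", c(pyr_c = -1, pyr_m = 1), "pyruvate transport, mitochondrial"),
    rx("PYRt_e", c(pyr_c = -1, pyr_e = 1), "pyruvate efflux"),
    rx("SUCCt_e", c(succ_c = -1, succ_e = 1), "succinate efflux"),
    rx("MALt", c(mal_c = -1, mal_m = 1), "malate transport, mitochondrial",
       lb = -1000),
    rx("FUMt", c(fum_m = -1, fum_c = 1), "fumarate transport", lb = -1000),
    rx("OAAt", c(oaa_c = -1, oaa_m = 1), "oxaloacetate transport"),
    rx("CITt", c(cit_m = -1, cit_c = 1), "citrate transport"),
    rx("PMAt", c(pma_c = -1, pma_e = 1), "PMA secretion"),
    rx("PIt", c(pi_c = -1, pi_m = 1), "phosphate transport", lb = -1000),
    rx("ATPt", c(atp_m = -1, adp_c = -1, atp_c = 1, adp_m = 1),
       "adenine nucleotide translocase"),
    rx("NADHt", c(nadh_c = -1, nad_m = -1, nad_c = 1, nadh_m = 1),
       "cytosolic NADH shuttle (lumped)"),
    # sugar entry and lumped glycolysis
    rx("INV", c(suc_c = -1, h2o_c = -1, glc_c = 1, fru_c = 1),
       "invertase (sucrose hydrolysis, no ATP cost)"),
    rx("GLYC", c(glc_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
                 pyr_c = 2, atp_c = 2, nadh_c = 2, h2o_c = 2),
       "glycolysis (lumped)"),
    rx("GLYCF", c(fru_c = -1, adp_c = -2, pi_c = -2, nad_c = -2,
                  pyr_c = 2, atp_c = 2, nadh_c = 2, h2o_c = 2),
       "fructose glycolysis (lumped)"),
    # oxidative TCA cycle, one reaction per enzyme
    rx("PDH", c(pyr_m = -1, coa_m = -1, nad_m = -1,
                accoa_m = 1, co2_m = 1, nadh_m = 1),
       "pyruvate dehydrogenase"),
    rx("CS", c(accoa_m = -1, oaa_m = -1, h2o_m = -1, cit_m = 1, coa_m = 1),
       "citrate synthase"),
    rx("ACONT", c(cit_m = -1, icit_m = 1), "aconitate hydratase",
       lb = -1000),
    rx("IDH", c(icit_m = -1, nad_m = -1, akg_m = 1, co2_m = 1, nadh_m = 1),
       "isocitrate dehydrogenase"),
    rx("AKGDH", c(akg_m = -1, coa_m = -1, nad_m = -1,
                  succoa_m = 1, co2_m = 1, nadh_m = 1),
       "oxoglutarate dehydrogenase"),
    rx("SUCOAS", c(succoa_m = -1, adp_m = -1, pi_m = -1,
                   succ_m = 1, atp_m = 1, coa_m = 1),
       "succinate-CoA ligase"),
    rx("SDH", c(succ_m = -1, fad_m = -1, fum_m = 1, fadh2_m = 1),
       "succinate dehydrogenase"),
    rx("FUM", c(fum_c = -1, h2o_c = -1, mal_c = 1), "fumarase",
       lb = -1000),
    rx("MDH_m", c(mal_m = -1, nad_m = -1, oaa_m = 1, nadh_m = 1),
       "malate dehydrogenase, mitochondrial", lb = -1000),
    # reductive cytosolic branch
    rx("PYC", c(pyr_c = -1, co2_c = -1, atp_c = -1, h2o_c = -1,
                oaa_c = 1, adp_c = 1, pi_c = 1),
       "pyruvate carboxylase"),
    rx("MDH_c", c(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1),
       "malate dehydrogenase, cytosolic", lb = -1000),
    # glyoxylate shunt and cytosolic support
    rx("ACONT_c", c(cit_c = -1, icit_c = 1), "aconitate hydratase, cytosolic",
       lb = -1000),
    rx("ICL", c(icit_c = -1, succ_c = 1, glx_c = 1), "isocitrate lyase"),
    rx("MAS", c(glx_c = -1, accoa_c = -1, h2o_c = -1, mal_c = 1, coa_c = 1),
       "malate synthase"),
    rx("ACL", c(cit_c = -1, atp_c = -1, coa_c = -1, h2o_c = -1,
                accoa_c = 1, oaa_c = 1, adp_c = 1, pi_c = 1),
       "ATP-citrate lyase"),
    rx("ASLY", c(oaa_c = -1, atp_c = -1, fum_c = 1, adp_c = 1, pi_c = 1),
       "aspartate-fumarate bypass (lumped purine/urea cycle)"),
    # energy metabolism
    rx("OXPHOS_N", c(nadh_m = -1, o2_c = -0.5, adp_m = -1.5, pi_m = -1.5,
                     nad_m = 1, atp_m = 1.5, h2o_m = 1.5),
       "oxidative phosphorylation, NADH (P/O 1.5)"),
    rx("OXPHOS_F", c(fadh2_m = -1, o2_c = -0.5, adp_m = -1, pi_m = -1,
                     fad_m = 1, atp_m = 1, h2o_m = 1),
       "oxidative phosphorylation, FADH2 (P/O 1.0)"),
    rx("ATPM", c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1),
       "ATP maintenance", lb = 0, ub = 1000),
    # product and biomass
    rx("PMAS", c(mal_c = -1, atp_c = -1,
                 pma_c = 1, adp_c = 1, pi_c = 1, h2o_c = 1),
       "PMA synthesis (malate polymerisation, 1 ATP per residue)"),
    rx("BIOMASS", c(pyr_c = -6, atp_c = -20, h2o_c = -20,
                    adp_c = 20, pi_c = 20, biomass_e = 1),
       "biomass (lumped pseudo-reaction)", kind = "biomass"))

  metabolic_model(
    mets, rxns, objective_id = "PMAS",
    notes = c(
      "Synthetic reduced central-carbon model of Aureobasidium pullulans.",
      "Glucose uptake <= 10 mmol/gDW/h; sucrose entry carbon- and energy-neutral.",
      "Lumped glycolysis: hexose -> 2 pyruvate + 2 ATP + 2 NADH.",
      "P/O = 1.5 (NADH), 1.0 (FADH2); ATP maintenance reaction present (lb 0); O2 uptake <= 20.",
      "PMA synthesis: malate + ATP -> PMA residue (C4H4O4) + ADP + Pi + H2O.",
      "CO2 exchange is reversible so the CO2-fixing carboxylase can run when decarboxylating routes are constrained off.",
      "Biomass: 6 pyruvate + 20 ATP per unit flux; biomass axis labelled gDW/h.",
      "H and O balanced only up to water/proton/phosphate bookkeeping species."))
}
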