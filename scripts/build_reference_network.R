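#!/usr/bin/env Rscript
# Maintainer script: (re)generate inst/extdata/adult_reference_network.json,
# the averaged-adult reference arterial tree shipped with the package.
# Geometry follows the classic 55-ish-segment averaged-adult topology used
# throughout 1D haemodynamics (aorta, arm, head, leg paths plus the main
# visceral branches), arranged as a strictly binary tree. Wall stiffness is
# set per region from reference pulse wave velocities; Windkessel terminals
# are calibrated to the reference mean working point (MAP 93.3 mmHg at
# 90 mL/s, i.e. cardiac output 5.4 L/min) with terminal flow fractions
# proportional to distal radius cubed (Murray's law) and a uniform
# peripheral time constant R2*C.
#
# Run from the repository root:  Rscript scripts/build_reference_network.R

source(file.path("R", "units.R"))
source(file.path("R", "network.R"))

seg <- read.csv(text = "
id,name,length,rp,rd,region,parent
asc_ao,ascending aorta,4.0,1.470,1.440,aortic,
arch_a,aortic arch A,2.0,1.120,1.120,aortic,asc_ao
brachioceph,brachiocephalic trunk,3.4,0.620,0.620,upper-limb,asc_ao
r_carotid,right common carotid,17.7,0.370,0.370,cerebral,brachioceph
r_carotid_int,right internal carotid,17.6,0.177,0.120,cerebral,r_carotid
r_carotid_ext,right external carotid,17.7,0.177,0.120,cerebral,r_carotid
r_subcl_a,right subclavian A,3.4,0.423,0.423,upper-limb,brachioceph
r_vertebral,right vertebral,14.8,0.188,0.183,cerebral,r_subcl_a
r_subcl_b,right subclavian B and brachial,42.2,0.403,0.236,upper-limb,r_subcl_a
r_radial,right radial,23.5,0.174,0.142,upper-limb,r_subcl_b
r_ulnar_a,right ulnar A,6.7,0.215,0.215,upper-limb,r_subcl_b
r_interosseous,right interosseous,7.9,0.091,0.091,upper-limb,r_ulnar_a
r_ulnar_b,right ulnar B,17.1,0.203,0.183,upper-limb,r_ulnar_a
l_carotid,left common carotid,20.8,0.370,0.370,cerebral,arch_a
l_carotid_int,left internal carotid,17.6,0.177,0.120,cerebral,l_carotid
l_carotid_ext,left external carotid,17.7,0.177,0.120,cerebral,l_carotid
arch_b,aortic arch B,3.9,1.070,1.050,aortic,arch_a
l_subcl_a,left subclavian A,3.4,0.423,0.423,upper-limb,arch_b
l_vertebral,left vertebral,14.8,0.188,0.183,cerebral,l_subcl_a
l_subcl_b,left subclavian B and brachial,42.2,0.403,0.236,upper-limb,l_subcl_a
l_radial,left radial,23.5,0.174,0.142,upper-limb,l_subcl_b
l_ulnar_a,left ulnar A,6.7,0.215,0.215,upper-limb,l_subcl_b
l_interosseous,left interosseous,7.9,0.091,0.091,upper-limb,l_ulnar_a
l_ulnar_b,left ulnar B,17.1,0.203,0.183,upper-limb,l_ulnar_a
thor_a,thoracic aorta A,5.2,1.000,0.950,aortic,arch_b
intercostal,intercostal trunk,8.0,0.200,0.200,visceral,thor_a
thor_b,thoracic aorta B,10.4,0.675,0.645,aortic,thor_a
abd_a,abdominal aorta A,5.3,0.610,0.600,aortic,thor_b
celiac_a,celiac A,2.0,0.390,0.390,visceral,abd_a
celiac_b,celiac B,1.0,0.200,0.200,visceral,celiac_a
hepatic,hepatic,6.6,0.220,0.220,visceral,celiac_a
gastric,gastric,7.1,0.180,0.180,visceral,celiac_b
splenic,splenic,6.3,0.275,0.275,visceral,celiac_b
abd_b,abdominal aorta B,1.0,0.600,0.590,aortic,abd_a
sup_mesenteric,superior mesenteric,5.9,0.435,0.435,visceral,abd_b
abd_c,abdominal aorta C,0.5,0.590,0.590,aortic,abd_b
l_renal,left renal,3.2,0.260,0.260,visceral,abd_c
abd_d,abdominal aorta D,0.5,0.590,0.585,aortic,abd_c
r_renal,right renal,3.2,0.260,0.260,visceral,abd_d
abd_e,abdominal aorta E,10.6,0.580,0.548,aortic,abd_d
inf_mesenteric,inferior mesenteric,5.0,0.160,0.160,visceral,abd_e
abd_f,abdominal aorta F,1.0,0.520,0.520,aortic,abd_e
l_com_iliac,left common iliac,5.8,0.370,0.360,aortic,abd_f
r_com_iliac,right common iliac,5.8,0.370,0.360,aortic,abd_f
l_ext_iliac,left external iliac,14.4,0.320,0.290,aortic,l_com_iliac
l_int_iliac,left internal iliac,5.0,0.200,0.200,lower-limb,l_com_iliac
r_ext_iliac,right external iliac,14.4,0.320,0.290,aortic,r_com_iliac
r_int_iliac,right internal iliac,5.0,0.200,0.200,lower-limb,r_com_iliac
l_femoral,left femoral,44.3,0.260,0.190,lower-limb,l_ext_iliac
l_deep_femoral,left deep femoral,12.6,0.255,0.186,lower-limb,l_ext_iliac
r_femoral,right femoral,44.3,0.260,0.190,lower-limb,r_ext_iliac
r_deep_femoral,right deep femoral,12.6,0.255,0.186,lower-limb,r_ext_iliac
l_post_tibial,left posterior tibial,32.1,0.247,0.141,lower-limb,l_femoral
l_ant_tibial,left anterior tibial,34.3,0.130,0.130,lower-limb,l_femoral
r_post_tibial,right posterior tibial,32.1,0.247,0.141,lower-limb,r_femoral
r_ant_tibial,right anterior tibial,34.3,0.130,0.130,lower-limb,r_femoral
", stringsAsFactors = FALSE, strip.white = TRUE)
seg$parent[seg$parent == ""] <- NA_character_

# Reference subject / working point
rho <- 1060          # kg/m^3
mu <- 0.004          # Pa s
ref_height <- 175    # cm
ref_weight <- 70     # kg
ref_bsa <- 0.007184 * ref_weight^0.425 * ref_height^0.725
ref_map <- 93 + 1 / 3          # 120/80 via the 2/3 rule
ref_flow <- 90                 # mL/s (CO 5.4 L/min)
p_ven <- 5                     # mmHg
tau_wk <- 1.3                  # peripheral Windkessel time constant R2*C (s)
# Transit-time identification constant of the foot-to-foot convention: the
# apparent foot transit speed of a simulated pulse exceeds the distended
# wave speed (pressure-dependent stiffening along the upstroke, advection by
# blood velocity, viscoelastic dispersion), so stiffness assignment targets
# measured-PWV / ftf_calibration. Determined once on the reference
# configuration so that the in-silico foot-to-foot measurement between the
# carotid and femoral sites reproduces the assigned carotid-femoral PWV.
ftf_calibration <- 1.18
regional_pwv <- list("aortic" = 5.86, "upper-limb" = 8.5, "cerebral" = 8.0,
                     "visceral" = 8.0, "lower-limb" = 9.0)

# Wall coefficients from the regional reference PWVs (mid-segment area),
# and mild Kelvin-Voigt damping scaling with vessel calibre.
a0_mid <- pi * ((seg$rp + seg$rd) / 2)^2
# Stiffness is referenced at the working pressure: a PWV measured in vivo
# holds at the vessel's distended state, so the distended wave speed at the
# reference MAP is what matches the regional target.
seg$wall_stiffness <- mapply(function(region, a0) {
  stiffness_from_pwv(regional_pwv[[region]] / ftf_calibration, a0, rho,
                     at_pressure = ref_map)
}, seg$region, a0_mid)
seg$viscoelastic_coeff <- 100 * sqrt(a0_mid)   # Pa s cm

names(seg)[names(seg) == "rp"] <- "proximal_radius"
names(seg)[names(seg) == "rd"] <- "distal_radius"

# Terminals: every leaf; total peripheral resistance matches the reference
# working point, flow split by Murray's law on distal radius.
leaves <- setdiff(seg$id, seg$parent[!is.na(seg$parent)])
rd_leaf <- seg$distal_radius[match(leaves, seg$id)]
frac <- rd_leaf^3 / sum(rd_leaf^3)
R_total <- (ref_map - p_ven) / ref_flow     # mmHg s / mL
R_i <- R_total / frac
A0_leaf <- pi * rd_leaf^2
c_leaf <- mapply(function(id, a0) {
  wave_speed(a0, a0, seg$wall_stiffness[seg$id == id], rho)
}, leaves, A0_leaf)
Zc <- (rho / 1000) * (c_leaf * 100) / A0_leaf / 1333.22387415  # mmHg s/mL
R1 <- pmin(Zc, 0.2 * R_i)
R2 <- R_i - R1
terminals <- data.frame(segment = leaves, R1 = R1, R2 = R2, C = tau_wk / R2,
                        venous_pressure = p_ven, stringsAsFactors = FALSE)

named_sites <- data.frame(
  site = c("aortic_root", "carotid", "brachial", "radial", "femoral", "tibial"),
  segment = c("asc_ao", "l_carotid", "l_subcl_b", "l_radial", "l_femoral",
              "l_post_tibial"),
  position = c(0.0, 0.02, 0.75, 0.9, 0.02, 0.9),
  stringsAsFactors = FALSE
)

net <- arterial_network(
  seg[, c("id", "name", "length", "proximal_radius", "distal_radius",
          "wall_stiffness", "viscoelastic_coeff", "region", "parent")],
  terminals, named_sites,
  fluid = list(blood_density = rho, blood_viscosity = mu),
  reference = list(height = ref_height, bsa = round(ref_bsa, 3),
                   map = ref_map, mean_flow = ref_flow,
                   ratio = ref_map / ref_flow,
                   ftf_calibration = ftf_calibration,
                   regional_pwv = regional_pwv)
)
out <- file.path("inst", "extdata", "adult_reference_network.json")
save_network(net, out)
cat("wrote", out, ":", nrow(net$segments), "segments,",
    nrow(net$terminals), "terminals\n")
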