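# Planar sit-to-walk musculoskeletal model (synthetic stand-in).
# 9 segments, 11 DOF, 20 Hill-type MTUs, 4 foot contact spheres, 1 buttock
# sphere, 1 chair box.  Segment inertial parameters are scaled from standard
# anthropometric tables to 1.80 m / 75 kg; muscle parameters are lumped-group
# values in the spirit of the classic lower-limb models; via-points are tuned
# for sign-correct, magnitude-plausible sagittal moment arms.
# Units: m, kg, deg.  Coordinate conventions: x forward, y up; hip/knee/ankle
# flexion (dorsiflexion) positive; pelvis anterior tilt positive.
model h1120_planar
gravity 9.81

segment pelvis  mass=8.0  inertia=0.08  com=0.0,-0.02  length=0.15
segment lumbar  mass=12.0 inertia=0.10  com=0.0,0.06   length=0.12
segment torso   mass=25.0 inertia=1.20  com=0.0,0.28   length=0.60
segment femur_r mass=10.5 inertia=0.16  com=0.0,-0.18  length=0.42
segment tibia_r mass=3.5  inertia=0.055 com=0.0,-0.19  length=0.43
segment foot_r  mass=1.0  inertia=0.007 com=0.06,-0.04 length=0.25
segment femur_l mass=10.5 inertia=0.16  com=0.0,-0.18  length=0.42
segment tibia_l mass=3.5  inertia=0.055 com=0.0,-0.19  length=0.43
segment foot_l  mass=1.0  inertia=0.007 com=0.06,-0.04 length=0.25

# free joint: pelvis_tx, pelvis_ty, pelvis_tilt (anterior tilt positive =>
# tilt_sign=-1 maps it onto the internal CCW angle)
joint ground_pelvis type=free parent=ground child=pelvis tilt_sign=-1
joint lumbar   type=pin parent=pelvis  child=lumbar  pos=0,0.08   sign=1  range=-60,10  limit_stiffness=500 limit_damping=0.5 passive=2.0
joint thoracic type=pin parent=lumbar  child=torso   pos=0,0.12   sign=1  range=-25,25  limit_stiffness=500 limit_damping=0.5 passive=2.0
joint hip_r    type=pin parent=pelvis  child=femur_r pos=0,-0.07  sign=1  range=-30,120 limit_stiffness=500 limit_damping=0.5 passive=0.3
joint knee_r   type=pin parent=femur_r child=tibia_r pos=0,-0.42  sign=-1 range=0,150   limit_stiffness=500 limit_damping=0.5 passive=0.3
joint ankle_r  type=pin parent=tibia_r child=foot_r  pos=0,-0.43  sign=1  range=-70,70  limit_stiffness=500 limit_damping=0.5 passive=0.3
joint hip_l    type=pin parent=pelvis  child=femur_l pos=0,-0.07  sign=1  range=-30,120 limit_stiffness=500 limit_damping=0.5 passive=0.3
joint knee_l   type=pin parent=femur_l child=tibia_l pos=0,-0.42  sign=-1 range=0,150   limit_stiffness=500 limit_damping=0.5 passive=0.3
joint ankle_l  type=pin parent=tibia_l child=foot_l  pos=0,-0.43  sign=1  range=-70,70  limit_stiffness=500 limit_damping=0.5 passive=0.3

# muscles: lslack calibrated so L (=l_ce/l_opt) is 1 at a mid-range
# reference posture (hip 45, knee 45, ankle 0, lumbar -10 deg)
muscle gmax_r fmax=1944 lopt=0.16 lslack=0.1112 vmax=10 side=r
viapoint gmax_r pelvis -0.08,0
viapoint gmax_r pelvis -0.061,-0.035
viapoint gmax_r femur_r -0.0739,-0.0129
viapoint gmax_r femur_r -0.01,-0.13
muscle ham_r fmax=2594 lopt=0.14 lslack=0.4259 vmax=10 side=r
viapoint ham_r pelvis -0.063,-0.029
viapoint ham_r femur_r -0.07,-0.015
viapoint ham_r femur_r -0.039,-0.398
viapoint ham_r tibia_r 0.032,-0.032
muscle bfsh_r fmax=600 lopt=0.12 lslack=0.0788 vmax=10 side=r
viapoint bfsh_r femur_r -0.025,-0.28
viapoint bfsh_r femur_r -0.041,-0.391
viapoint bfsh_r tibia_r 0.032,-0.038
muscle iliac_r fmax=1073 lopt=0.12 lslack=0.0603 vmax=10 side=r
viapoint iliac_r pelvis 0.045,0.09
viapoint iliac_r pelvis 0.026,0.027
viapoint iliac_r femur_r 0.0275,-0.0476
muscle psoas_r fmax=1113 lopt=0.13 lslack=0.0894 vmax=10 side=r
viapoint psoas_r pelvis 0.04,0.13
viapoint psoas_r pelvis 0.019,0.038
viapoint psoas_r femur_r 0.034,-0.049
muscle rfem_r fmax=1169 lopt=0.12 lslack=0.4032 vmax=10 side=r
viapoint rfem_r pelvis 0.034,0.024
viapoint rfem_r femur_r 0.021,-0.045
viapoint rfem_r femur_r 0.047,-0.403
viapoint rfem_r tibia_r 0.055,0.005
muscle vas_r fmax=4530 lopt=0.15 lslack=0.1858 vmax=10 side=r
viapoint vas_r femur_r 0.035,-0.12
viapoint vas_r femur_r 0.047,-0.403
viapoint vas_r tibia_r 0.055,0.005
muscle gas_r fmax=1601 lopt=0.09 lslack=0.4077 vmax=10 side=r
viapoint gas_r femur_r -0.027,-0.407
viapoint gas_r tibia_r 0.018,-0.018
viapoint gas_r tibia_r -0.035,-0.395
viapoint gas_r foot_r -0.035,-0.035
muscle sol_r fmax=3549 lopt=0.08 lslack=0.2351 vmax=10 side=r
viapoint sol_r tibia_r -0.027,-0.15
viapoint sol_r tibia_r -0.035,-0.395
viapoint sol_r foot_r -0.035,-0.035
muscle ta_r fmax=905 lopt=0.08 lslack=0.202 vmax=10 side=r
viapoint ta_r tibia_r 0.032,-0.18
viapoint ta_r tibia_r 0.032,-0.398
viapoint ta_r foot_r 0.032,-0.032
muscle gmax_l fmax=1944 lopt=0.16 lslack=0.1112 vmax=10 side=l
viapoint gmax_l pelvis -0.08,0
viapoint gmax_l pelvis -0.061,-0.035
viapoint gmax_l femur_l -0.0739,-0.0129
viapoint gmax_l femur_l -0.01,-0.13
muscle ham_l fmax=2594 lopt=0.14 lslack=0.4259 vmax=10 side=l
viapoint ham_l pelvis -0.063,-0.029
viapoint ham_l femur_l -0.07,-0.015
viapoint ham_l femur_l -0.039,-0.398
viapoint ham_l tibia_l 0.032,-0.032
muscle bfsh_l fmax=600 lopt=0.12 lslack=0.0788 vmax=10 side=l
viapoint bfsh_l femur_l -0.025,-0.28
viapoint bfsh_l femur_l -0.041,-0.391
viapoint bfsh_l tibia_l 0.032,-0.038
muscle iliac_l fmax=1073 lopt=0.12 lslack=0.0603 vmax=10 side=l
viapoint iliac_l pelvis 0.045,0.09
viapoint iliac_l pelvis 0.026,0.027
viapoint iliac_l femur_l 0.0275,-0.0476
muscle psoas_l fmax=1113 lopt=0.13 lslack=0.0894 vmax=10 side=l
viapoint psoas_l pelvis 0.04,0.13
viapoint psoas_l pelvis 0.019,0.038
viapoint psoas_l femur_l 0.034,-0.049
muscle rfem_l fmax=1169 lopt=0.12 lslack=0.4032 vmax=10 side=l
viapoint rfem_l pelvis 0.034,0.024
viapoint rfem_l femur_l 0.021,-0.045
viapoint rfem_l femur_l 0.047,-0.403
viapoint rfem_l tibia_l 0.055,0.005
muscle vas_l fmax=4530 lopt=0.15 lslack=0.1858 vmax=10 side=l
viapoint vas_l femur_l 0.035,-0.12
viapoint vas_l femur_l 0.047,-0.403
viapoint vas_l tibia_l 0.055,0.005
muscle gas_l fmax=1601 lopt=0.09 lslack=0.4077 vmax=10 side=l
viapoint gas_l femur_l -0.027,-0.407
viapoint gas_l tibia_l 0.018,-0.018
viapoint gas_l tibia_l -0.035,-0.395
viapoint gas_l foot_l -0.035,-0.035
muscle sol_l fmax=3549 lopt=0.08 lslack=0.2351 vmax=10 side=l
viapoint sol_l tibia_l -0.027,-0.15
viapoint sol_l tibia_l -0.035,-0.395
viapoint sol_l foot_l -0.035,-0.035
muscle ta_l fmax=905 lopt=0.08 lslack=0.202 vmax=10 side=l
viapoint ta_l tibia_l 0.032,-0.18
viapoint ta_l tibia_l 0.032,-0.398
viapoint ta_l foot_l 0.032,-0.032

# contact: feet on ground (plane-strain modulus 17500 N/m^2), buttock vs
# chair box (10000 N/m^2); dissipation 1 s/m, friction 0.9 static / 0.6 dynamic
sphere heel_r segment=foot_r pos=-0.06,-0.045 radius=0.03 modulus=17500 dissipation=1 mu_s=0.9 mu_d=0.6 role=foot
sphere toe_r  segment=foot_r pos=0.19,-0.045  radius=0.03 modulus=17500 dissipation=1 mu_s=0.9 mu_d=0.6 role=foot
sphere heel_l segment=foot_l pos=-0.06,-0.045 radius=0.03 modulus=17500 dissipation=1 mu_s=0.9 mu_d=0.6 role=foot
sphere toe_l  segment=foot_l pos=0.19,-0.045  radius=0.03 modulus=17500 dissipation=1 mu_s=0.9 mu_d=0.6 role=foot
sphere buttock segment=pelvis pos=-0.02,-0.05 radius=0.12 modulus=10000 dissipation=1 mu_s=0.9 mu_d=0.6 role=buttock
box chair size=0.40,0.12 modulus=10000 dissipation=1 mu_s=0.9 mu_d=0.6

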