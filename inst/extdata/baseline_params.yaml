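# Baseline parameterization of the hepatic cholesterol model.
# Units: first-order constants 1/min, bimolecular constants uL/(umol*min),
# Vmax uMoles/min, Km umol/uL, time min.  provenance "appendix" marks the
# three constants printed in the source parameterization; everything else is
# "calibrated" against the shipped anchor set (anchors.csv).
constants:
  k1:          {value: 0.1, provenance: appendix}
  k2f:         {value: 0.0020334763, provenance: calibrated}
  k2r:         {value: 0.1000018, provenance: calibrated}
  k3:          {value: 0.0099853096, provenance: calibrated}
  vmax_r4:     {value: 1.43, provenance: appendix}
  km_r4:       {value: 14.760008, provenance: calibrated}
  ros_gain_r4: {value: 0, provenance: calibrated}
  k5:          {value: 0.017093487, provenance: calibrated}
  k6f:         {value: 0.079890096, provenance: calibrated}
  k6r:         {value: 0.088647892, provenance: calibrated}
  k7:          {value: 0.017028512, provenance: calibrated}
  k8f:         {value: 0.44451659, provenance: calibrated}
  k8r:         {value: 1.7013553, provenance: calibrated}
  k9:          {value: 0.93399919, provenance: calibrated}
  k10:         {value: 1.8537002, provenance: calibrated}
  k11:         {value: 0.017426637, provenance: calibrated}
  k12:         {value: 0.017325914, provenance: calibrated}
  k13:         {value: 0.017860527, provenance: calibrated}
  k14:         {value: 0.0059941034, provenance: calibrated}
  vmax_r15:    {value: 0.04, provenance: appendix}
  km_r15:      {value: 4.0030671, provenance: calibrated}
  k16:         {value: 0.00010659609, provenance: calibrated}
  k17:         {value: 0.099883558, provenance: calibrated}
  k18:         {value: 0.099870304, provenance: calibrated}
  k19:         {value: 157.54309, provenance: calibrated}
  k19_basal:   {value: 17.5, provenance: calibrated}
  k20:         {value: 0.0050068786, provenance: calibrated}
  k21:         {value: 0.00000000143, provenance: calibrated}
  k22:         {value: 0.0502, provenance: calibrated}
  ki_fc:       {value: 748.93704, provenance: calibrated}
  k23:         {value: 0.05, provenance: calibrated}
  k24:         {value: 0.008, provenance: calibrated}
  k24_basal:   {value: 0.002, provenance: calibrated}
  k25:         {value: 0.01, provenance: calibrated}
  k26:         {value: 0.01, provenance: calibrated}
  k27:         {value: 0.01, provenance: calibrated}
  k28:         {value: 0.01, provenance: calibrated}
  k29:         {value: 0.01, provenance: calibrated}
  k30:         {value: 0.01, provenance: calibrated}
initial:
  ACoA: 0.2305885
  AACoA: 0
  HMGCoA: 0
  MV: 0
  MV5P: 0
  MV5PP: 0
  IPP: 0
  DMAPP: 0
  GPP: 0
  FPP: 0
  SQ: 0
  SQE: 0
  LAN: 0
  FC: 7.672737
  CE: 0
  LDLC: 0
  LDLR: 0
  SRBP2: 1
  AOX: 1
  ROS: 1
  HMGCoAR: 1
  ACAT2: 1
  CoAS: 0.99620099
  LDLCs: 0
  sLDLR: 1
  dLDLR: 0
  sSRBP2: 1
  dSRBP2: 0
  sAOX: 1
  sROS: 1
  ROSsink: 0
  sHMGCoAR: 1
  dHMGCoAR: 0
  sACAT2: 1
  dACAT2: 0
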