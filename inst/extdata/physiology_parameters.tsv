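# Versioned mirror of the physiological constants and equations used by the
# physiology module (version 0.1.0).  Ages in postnatal years unless noted.
parameter	value_or_equation	units	cv_pct	age_range	note
v_brain_total	(10*a+0.315)/(9+6.92*a)/1.04, a = age+0.75 (years since conception)	L	0	0-80	brain weight relation / brain density 1.04
v_brain_blood	0.05*v_brain_total	L	0	0-80
v_endothelial	0.005*v_brain_total	L	0	0-80
v_ccsf	0.143	L	0	0-80	cranial CSF constant after birth
v_scsf	(1.94*BW+0.13)/1000, capped at 0.25*v_ccsf	L	0	0-80	spinal CSF <= 20% of total CSF (cranial = 80%)
v_brain_mass	v_brain_total - v_endothelial - v_brain_blood - v_ccsf - v_scsf	L	0	0-80
q_csfprod	0.024	L/h	10	0.25-80	doubled under spinal ketamine anesthesia
q_csfprod_lt3m	(4.007*ln(age_days)+7.088)/1000	L/h	10	0-0.25	natural log, postnatal days
q_bulk	0.25*q_csfprod	L/h	8	0-80	brain mass -> cranial CSF
q_ssink	0.38*(0.75*q_csfprod+q_bulk)	L/h	30	0-80	spinal CSF -> blood
q_sout	0.9*q_ssink	L/h	100	0-80	spinal -> cranial shuttle
q_sin	q_ssink+q_sout	L/h	0	0-80	cranial -> spinal shuttle
q_csink	0.75*q_csfprod+q_bulk-q_sin+q_sout	L/h	0	0-80	cranial CSF -> blood; closes q_csink+q_ssink=q_csfprod
q_brain	cardiac_output*(10+2290*(10^(-0.608*age)-10^(-0.639*age)))/100	L/h	0	0-80	fraction of cardiac output
bbb_surface_adult	15	m2	0	adult	scaled by v_brain_total child/adult ratio
adult_ref_age	35	y	0	-	reference age for child/adult scaling
cardiac_output	(3.2+1.0*exp(-age/5))*BSA*60	L/h	0	0-80	cardiac index * BSA
hematocrit	piecewise linear 0.47 (birth), 0.33 (3 m), 0.42 (adult)	fraction	0	0-80
albumin	piecewise linear 35 (birth) - 45 (adult)	g/L	0	0-80
weight	sex-specific growth reference, monotone spline	kg	13	0-80	log-normal residual
height	sex-specific growth reference, monotone spline	cm	3.5	0-80	log-normal residual
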