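pattern,category
W00,fall
W01,fall
W02,fall
W03,fall
W04,fall
W05,fall
W06,fall
W07,fall
W08,fall
W09,fall
W10,fall
W11,fall
W12,fall
W13,fall
W14,fall
W15,fall
W16,fall
W17,fall
W18,fall
W19,fall
W20,struck_by_against
W21,struck_by_against
W22,struck_by_against
W50,struck_by_against
W51,struck_by_against
W52,struck_by_against
W24,machinery
W30,machinery
W31,machinery
W25,cut_pierce
W26,cut_pierce
W27,cut_pierce
W28,cut_pierce
W29,cut_pierce
W45,cut_pierce
W46,cut_pierce
W32,firearm
W33,firearm
W34,firearm
W53,environmental
W54,environmental
W55,environmental
W56,environmental
W57,environmental
W58,environmental
W59,environmental
W60,environmental
W61,environmental
W62,environmental
W63,environmental
W64,environmental
W92,environmental
W93,environmental
W94,environmental
W95,environmental
W96,environmental
W97,environmental
W98,environmental
W99,environmental
X20,environmental
X21,environmental
X22,environmental
X23,environmental
X24,environmental
X25,environmental
X26,environmental
X27,environmental
X28,environmental
X29,environmental
X30,environmental
X31,environmental
X32,environmental
X33,environmental
X34,environmental
X35,environmental
X36,environmental
X37,environmental
X38,environmental
X39,environmental
W65,drowning
W66,drowning
W67,drowning
W68,drowning
W69,drowning
W70,drowning
W71,drowning
W72,drowning
W73,drowning
W74,drowning
W75,suffocation
W76,suffocation
W77,suffocation
W78,suffocation
W79,suffocation
W80,suffocation
W81,suffocation
W82,suffocation
W83,suffocation
W84,suffocation
W85,other
W86,other
W87,other
W88,other
W89,other
W90,other
W91,other
X52,other
X58,other
X00,fire_burn
X01,fire_burn
X02,fire_burn
X03,fire_burn
X04,fire_burn
X05,fire_burn
X06,fire_burn
X07,fire_burn
X08,fire_burn
X09,fire_burn
X10,fire_burn
X11,fire_burn
X12,fire_burn
X13,fire_burn
X14,fire_burn
X15,fire_burn
X16,fire_burn
X17,fire_burn
X18,fire_burn
X19,fire_burn
V02,motor_vehicle_traffic
V03,motor_vehicle_traffic
V04,motor_vehicle_traffic
V09,motor_vehicle_traffic
V12,motor_vehicle_traffic
V13,motor_vehicle_traffic
V14,motor_vehicle_traffic
V20,motor_vehicle_traffic
V21,motor_vehicle_traffic
V22,motor_vehicle_traffic
V23,motor_vehicle_traffic
V24,motor_vehicle_traffic
V25,motor_vehicle_traffic
V26,motor_vehicle_traffic
V27,motor_vehicle_traffic
V28,motor_vehicle_traffic
V29,motor_vehicle_traffic
V30,motor_vehicle_traffic
V31,motor_vehicle_traffic
V32,motor_vehicle_traffic
V33,motor_vehicle_traffic
V34,motor_vehicle_traffic
V35,motor_vehicle_traffic
V36,motor_vehicle_traffic
V37,motor_vehicle_traffic
V38,motor_vehicle_traffic
V39,motor_vehicle_traffic
V40,motor_vehicle_traffic
V41,motor_vehicle_traffic
V42,motor_vehicle_traffic
V43,motor_vehicle_traffic
V44,motor_vehicle_traffic
V45,motor_vehicle_traffic
V46,motor_vehicle_traffic
V47,motor_vehicle_traffic
V48,motor_vehicle_traffic
V49,motor_vehicle_traffic
V50,motor_vehicle_traffic
V51,motor_vehicle_traffic
V52,motor_vehicle_traffic
V53,motor_vehicle_traffic
V54,motor_vehicle_traffic
V55,motor_vehicle_traffic
V56,motor_vehicle_traffic
V57,motor_vehicle_traffic
V58,motor_vehicle_traffic
V59,motor_vehicle_traffic
V60,motor_vehicle_traffic
V61,motor_vehicle_traffic
V62,motor_vehicle_traffic
V63,motor_vehicle_traffic
V64,motor_vehicle_traffic
V65,motor_vehicle_traffic
V66,motor_vehicle_traffic
V67,motor_vehicle_traffic
V68,motor_vehicle_traffic
V69,motor_vehicle_traffic
V70,motor_vehicle_traffic
V71,motor_vehicle_traffic
V72,motor_vehicle_traffic
V73,motor_vehicle_traffic
V74,motor_vehicle_traffic
V75,motor_vehicle_traffic
V76,motor_vehicle_traffic
V77,motor_vehicle_traffic
V78,motor_vehicle_traffic
V79,motor_vehicle_traffic
V01,transportation_other
V05,transportation_other
V06,transportation_other
V10,transportation_other
V11,transportation_other
V15,transportation_other
V16,transportation_other
V17,transportation_other
V18,transportation_other
V80,transportation_other
V81,transportation_other
V82,transportation_other
V83,transportation_other
V84,transportation_other
V85,transportation_other
V86,transportation_other
V87,transportation_other
V88,transportation_other
V89,transportation_other
V90,transportation_other
V91,transportation_other
V92,transportation_other
V93,transportation_other
V94,transportation_other
V95,transportation_other
V96,transportation_other
V97,transportation_other
V98,transportation_other
V99,transportation_other
X40,poisoning_drug
X41,poisoning_drug
X42,poisoning_drug
X43,poisoning_drug
X44,poisoning_drug
X45,poisoning_nondrug
X46,poisoning_nondrug
X47,poisoning_nondrug
X48,poisoning_nondrug
X49,poisoning_nondrug
X50,overexertion
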