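genome_id	n_cif_operons	n_orphan_cifA	n_orphan_cifB	n_wmk
w.brenthis_hecate.BH_1412	1	1	1	3
w.colias_alfacariensis.CA_966	1	0	0	2
w.colias_hyale.CH_1004	6	0	1	1
w.erebia_ligea.EE_932	2	0	0	4
w.erebia_ligea.RO_EL_949	1	1	0	3
w.gonepteryx_cleopatra.GR_164	1	3	1	3
w.iphiclides_feisthamelii.IF_142	2	0	0	2
w.iphiclides_podalirius.IP_504	1	0	0	1
w.lasiommata_petropolitana.LP_1401	3	0	0	1
w.polyommatus_eros.PE_1417	2	2	2	2
w.pontia_edusa.RO_PE_757	2	0	0	0
w.thymelicus_acteon.SP_TA_344	3	1	2	6
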