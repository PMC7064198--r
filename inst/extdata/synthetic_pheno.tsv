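id	bmi	age	packyears
sample01	27.059	45.8	15.3
sample02	30.493	36.3	45.8
sample03	22.888	52.3	14.8
sample04	29.743	57	30
sample05	28.798	56.1	29.2
sample06	28.628	46.6	42.7
sample07	28.139	47.9	45.4
sample08	24.503	58.7	10.6
sample09	30.359	58.5	36.3
sample10	28.245	54.7	31.6
sample11	28.901	44.9	26
sample12	26.6	57.9	40.7
sample13	27.814	58.2	11.6
sample14	26.624	50.3	0.9
sample15	27.401	47.1	6.4
sample16	25.927	51.8	6.2
sample17	32.384	67.5	21.9
sample18	26.414	30.7	17.4
sample19	27.199	58	10.5
sample20	30.335	51.3	3.9
sample21	25.836	67.2	26.3
sample22	22.661	44.2	21.8
sample23	30.757	44.3	30.2
sample24	28.443	37.7	16.3
sample25	29.961	57.4	19.4
sample26	30.528	64.9	0
sample27	29.115	63.4	0
sample28	18.799	56.5	45.9
sample29	30.929	62.4	7.3
sample30	28.894	48.2	0
sample31	30.282	50.2	16.5
sample32	29.36	56	13.1
sample33	23.752	66.8	29.6
sample34	31.081	67.1	11.8
sample35	33.21	60.3	30.5
sample36	30.936	57.1	38.9
sample37	26.526	48.1	23.6
sample38	22.149	50.4	25.2
sample39	29.645	48.8	41.4
sample40	25.775	54.9	26.6
sample41	27.321	49.8	12
sample42	27.33	59.1	35.8
sample43	23.29	53.2	4.6
sample44	26.519	52.7	32.7
sample45	23.498	55.9	46.3
sample46	20.593	50.1	0
sample47	22.401	55.6	22.3
sample48	24.54	58.7	33.3
sample49	24.429	55.7	0
sample50	22.006	57.1	12.1
sample51	28.5	49.1	12.6
sample52	26.221	45.3	27.2
sample53	25.11	71	15.2
sample54	26.748	45.1	21.6
sample55	20.887	54.9	30.1
sample56	24.047	36.6	24.7
sample57	30.083	69.7	18.3
sample58	26.246	51.3	10.6
sample59	30.531	45.8	24
sample60	24.602	55.3	0
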